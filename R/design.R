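#' Fixed- and random-effect specifications for the growth model
#'
#' A fixed-effect spec maps each growth parameter (`a_mat`, `r`, `beta`) to a
#' one-sided formula in the treatment factors `line` and `food`, e.g.
#' `growth_spec(a_mat = ~ line * food, r = ~ food, beta = ~ food)` (the
#' best-ranked female structure). Treatment contrasts use the reference level
#' large-selected line x high food, so the intercept row is that group and
#' the remaining coefficients are additive effects on the natural parameter
#' scale. An interaction requires both main effects (marginality).
#'
#' @param a_mat,r,beta One-sided formulas with terms drawn from
#'   `~ 1`, `~ line`, `~ food`, `~ line + food`, `~ line * food`.
#' @return An object of class `growth_spec`.
#' @export
growth_spec <- function(a_mat = ~1, r = ~1, beta = ~1) {
  spec <- list(a_mat = a_mat, r = r, beta = beta)
  for (nm in names(spec)) {
    f <- spec[[nm]]
    stopifnot(inherits(f, "formula"), length(f) == 2)
    tl <- attr(stats::terms(f), "term.labels")
    bad <- setdiff(tl, c("line", "food", "line:food"))
    if (length(bad)) stop("unsupported term(s) for ", nm, ": ", paste(bad, collapse = ", "))
    if ("line:food" %in% tl && !all(c("line", "food") %in% tl))
      stop("interaction for ", nm, " requires both main effects")
  }
  structure(spec, class = "growth_spec")
}

#' @describeIn growth_spec Best-ranked published structures: female
#'   `a_mat ~ line * food, r ~ food, beta ~ food` (8 coefficients); male
#'   `a_mat ~ food, r ~ food, beta ~ line + food` (7 coefficients).
#' @param sex `"F"` or `"M"`.
#' @export
default_growth_spec <- function(sex = c("F", "M")) {
  sex <- match.arg(sex)
  if (sex == "F") growth_spec(a_mat = ~ line * food, r = ~food, beta = ~food)
  else growth_spec(a_mat = ~food, r = ~food, beta = ~ line + food)
}

#' Random-effect specification
#'
#' Individual-level Gaussian intercepts on growth parameters, on the natural
#' parameter scale. Published defaults: females carry a random effect on
#' `beta` only; males on `r` and `beta`.
#'
#' @param params Character subset of `c("a_mat", "r", "beta")`.
#' @return Character vector of class `growth_random_spec`.
#' @export
growth_random_spec <- function(params = "beta") {
  stopifnot(all(params %in% c("a_mat", "r", "beta")), !anyDuplicated(params))
  structure(params, class = "growth_random_spec")
}

#' @describeIn growth_random_spec Published default per sex.
#' @param sex `"F"` or `"M"`.
#' @export
default_growth_random_spec <- function(sex = c("F", "M")) {
  sex <- match.arg(sex)
  if (sex == "F") growth_random_spec("beta") else growth_random_spec(c("r", "beta"))
}

# Canonical treatment factors: reference large_selected line, high food.
treatment_factors <- function(tbl) {
  tbl$line <- factor(tbl$line, levels = c("large_selected", "small_selected"))
  tbl$food <- factor(tbl$food, levels = c("high", "low"))
  if (anyNA(tbl$line)) stop("unknown line level; expected large_selected/small_selected")
  if (anyNA(tbl$food)) stop("unknown food level; expected high/low")
  tbl
}

#' Expand a fixed-effect spec into per-fish parameter maps
#'
#' For each growth parameter, builds the treatment-contrast model matrix
#' (reference large-selected x high food) with one row per fish, so that
#' natural-scale parameter values are `X %*% coef`.
#'
#' @param tbl Trajectory table with `fish_id`, `line`, `food`.
#' @param spec A [growth_spec()].
#' @return List with `fish` (one row per fish: id, line, food), per-parameter
#'   model matrices `X` (named list), coefficient names `coef_names`, and
#'   `n_coef`.
#' @export
build_design <- function(tbl, spec) {
  stopifnot(inherits(spec, "growth_spec"))
  tbl <- treatment_factors(tbl)
  fish <- unique(tbl[, c("fish_id", "line", "food")])
  fish <- fish[order(fish$fish_id), , drop = FALSE]
  rownames(fish) <- NULL
  X <- lapply(spec, function(f) stats::model.matrix(f, data = fish))
  coef_names <- unlist(lapply(names(X), function(p)
    paste(p, colnames(X[[p]]), sep = ".")), use.names = FALSE)
  list(fish = fish, X = X, coef_names = coef_names,
       n_coef = sum(vapply(X, ncol, integer(1))))
}

# Natural-scale parameter values per fish implied by a coefficient vector
# ordered as build_design()$coef_names.
design_param_values <- function(design, coefs) {
  stopifnot(length(coefs) == design$n_coef)
  out <- list(); i <- 0
  for (p in names(design$X)) {
    k <- ncol(design$X[[p]])
    out[[p]] <- unname(drop(design$X[[p]] %*% coefs[i + seq_len(k)]))
    i <- i + k
  }
  out
}
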