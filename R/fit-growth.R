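#' Fit the biphasic growth model by nonlinear mixed-effects
#'
#' Estimates age at maturation (`a_mat`), reproductive investment (`r`) and
#' the allometric growth exponent (`beta`) from longitudinal length-at-age
#' data, with treatment effects (selection line, food, their interaction)
#' entering additively on the natural parameter scale, individual Gaussian
#' random effects on the parameters named in `random_spec`, and an MA(2)
#' (ARMA(0,2)) correlation structure over consecutive within-fish
#' measurement occasions. Estimation is maximum likelihood via
#' [nlme::nlme()] (Lindstrom-Bates); with an empty random spec the model
#' collapses to generalized nonlinear least squares ([nlme::gnls()]), and
#' with `use_ma2 = FALSE` as well, to plain nonlinear least squares.
#'
#' The weight-length allometry (alpha, b), the growth-rate coefficient `c`
#' and hatch length `L0` are held fixed, as in the pre-estimation workflow:
#' estimate (alpha, b) and L0 from the data first, then condition the
#' nonlinear fit on them.
#'
#' @param tbl Trajectory table: `fish_id`, `line`, `food`, `age` (dph),
#'   `length` (mm). Fish with fewer than 4 measurements are dropped.
#' @param spec A [growth_spec()] fixed-effect structure.
#' @param random_spec A [growth_random_spec()]; may be empty.
#' @param c,L0 Fixed growth-rate coefficient (mg^(1-beta)/day) and hatch
#'   length (mm).
#' @param ap [allometry_params()] held fixed during the fit.
#' @param use_ma2 Include the MA(2) residual correlation (default TRUE).
#' @param start Optional numeric start vector for the fixed coefficients (in
#'   [build_design()] order); computed from the data when `NULL`.
#' @param control Passed to [nlme::nlmeControl()] / [nlme::gnlsControl()].
#' @return An object of class `growth_fit`: coefficient table (`term`,
#'   `estimate`, `se`, `df`, `t`, `p`), `logLik`, `AIC`, `sigma`, MA
#'   coefficients `theta`, random-effect SDs `re_sd`, per-group parameter
#'   table `group_params`, `converged` flag, and the underlying nlme fit.
#' @export
fit_growth <- function(tbl, spec, random_spec = growth_random_spec("beta"),
                       c = 0.15, L0 = 4.0, ap = allometry_params(),
                       use_ma2 = TRUE, start = NULL, control = list()) {
  stopifnot(inherits(spec, "growth_spec"))
  for (col in c("fish_id", "line", "food", "age", "length"))
    if (!col %in% names(tbl)) stop("trajectory table lacks column '", col, "'")
  tbl <- treatment_factors(tbl)
  tbl <- tbl[!is.na(tbl$length), , drop = FALSE]
  keep <- names(which(table(tbl$fish_id) >= 4))
  if (!length(keep)) stop("no fish with at least 4 measurements")
  tbl <- tbl[tbl$fish_id %in% keep, , drop = FALSE]
  tbl <- tbl[order(tbl$fish_id, tbl$age), , drop = FALSE]
  tbl$fish_id <- factor(tbl$fish_id)

  if (is.null(start))
    start <- growth_start_values(tbl, spec, c = c, L0 = L0, ap = ap)

  model <- stats::as.formula(
    substitute(length ~ biphasic_length_v(age, a_mat, r, beta,
                                          c = CC, L0 = LL, alpha = AA, b = BB),
               list(CC = c, LL = L0, AA = ap$alpha, BB = ap$b)),
    env = environment(biphasic_length_v))
  fixed_forms <- lapply(names(spec), function(p)
    stats::as.formula(paste(p, paste(deparse(spec[[p]]), collapse = "")),
                      env = environment(biphasic_length_v)))
  corr <- if (use_ma2)
    nlme::corARMA(value = c(0.2, 0.05), p = 0, q = 2, form = ~ 1 | fish_id)
  else NULL

  warn <- character(0)
  collect <- function(w) { warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning") }
  fit <- withCallingHandlers({
    if (length(random_spec) == 0) {
      ctrl <- utils::modifyList(
        list(maxIter = 200, nlsMaxIter = 25, returnObject = TRUE), control)
      nlme::gnls(model, data = tbl, params = fixed_forms, start = start,
                 correlation = corr, control = do.call(nlme::gnlsControl, ctrl))
    } else {
      rand_form <- stats::as.formula(
        paste(paste(unclass(random_spec), collapse = " + "), "~ 1"))
      ctrl <- utils::modifyList(
        list(maxIter = 200, pnlsMaxIter = 25, msMaxIter = 200,
             returnObject = TRUE, tolerance = 1e-6), control)
      nlme::nlme(model, data = tbl, fixed = fixed_forms,
                 random = nlme::pdDiag(rand_form), groups = ~fish_id,
                 start = start, correlation = corr, method = "ML",
                 control = do.call(nlme::nlmeControl, ctrl))
    }
  }, warning = collect)

  as_growth_fit(fit, tbl, spec, random_spec, c = c, L0 = L0, ap = ap,
                use_ma2 = use_ma2, warnings = warn)
}

# Wrap an nlme/gnls fit into the growth_fit container.
as_growth_fit <- function(fit, tbl, spec, random_spec, c, L0, ap, use_ma2,
                          warnings = character(0)) {
  sm <- summary(fit)
  tt <- sm$tTable
  coef_table <- data.frame(
    term = rownames(tt),
    estimate = tt[, "Value"],
    se = tt[, "Std.Error"],
    df = if ("DF" %in% colnames(tt)) tt[, "DF"] else NA_real_,
    t = tt[, "t-value"],
    p = tt[, "p-value"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  theta <- c(theta1 = 0, theta2 = 0)
  cs <- fit$modelStruct$corStruct
  if (!is.null(cs)) {
    th <- stats::coef(cs, unconstrained = FALSE)
    theta <- c(theta1 = unname(th[1]), theta2 = unname(th[2]))
  }
  re_sd <- numeric(0)
  if (length(random_spec) > 0) {
    vc <- nlme::VarCorr(fit)
    rn <- rownames(vc)
    re_sd <- vapply(unclass(random_spec), function(p) {
      row <- which(rn == p | rn == paste0(p, ".(Intercept)"))[1]
      suppressWarnings(as.numeric(vc[row, "StdDev"]))
    }, numeric(1))
  }
  design <- build_design(tbl, spec)
  k_fixed <- design$n_coef
  cf <- if (inherits(fit, "gnls")) stats::coef(fit) else nlme::fixef(fit)
  group_params <- group_param_table(tbl, spec, cf, stats::vcov(fit))
  structure(list(
    coef_table = coef_table,
    logLik = as.numeric(stats::logLik(fit)),
    AIC = stats::AIC(fit),
    n_params = attr(stats::logLik(fit), "df"),
    sigma = fit$sigma,
    theta = theta,
    re_sd = re_sd,
    group_params = group_params,
    spec = spec,
    random_spec = random_spec,
    constants = list(c = c, L0 = L0, alpha = ap$alpha, b = ap$b),
    use_ma2 = use_ma2,
    n_obs = nrow(tbl),
    n_fish = length(unique(tbl$fish_id)),
    converged = !any(grepl("without convergence|maximum number of iterations",
                           warnings, ignore.case = TRUE)),
    warnings = warnings,
    data = tbl,
    fit = fit
  ), class = "growth_fit")
}

# Per-group natural-scale parameter values and SEs implied by the fixed
# coefficients (Table-1/3-shaped summary): value = x_g' beta_p, SE from the
# corresponding block of the fixed-effect covariance.
group_param_table <- function(tbl, spec, coefs, vcov_fixed) {
  gf <- unique(treatment_factors(tbl)[, c("line", "food")])
  gf <- gf[order(gf$food, gf$line), , drop = FALSE]
  rownames(gf) <- NULL
  out <- gf
  i <- 0
  for (p in names(spec)) {
    X <- stats::model.matrix(spec[[p]], gf)
    idx <- i + seq_len(ncol(X))
    out[[p]] <- drop(X %*% coefs[idx])
    V <- vcov_fixed[idx, idx, drop = FALSE]
    out[[paste0(p, "_se")]] <- sqrt(pmax(rowSums((X %*% V) * X), 0))
    i <- i + ncol(X)
  }
  out
}

#' Data-driven starting values for the growth fit
#'
#' Two-stage heuristic: per treatment group, (1) initial values from the
#' group mean trajectory (beta from the juvenile-phase log-log slope of
#' growth rate against weight, a_mat from the age at which the per-day
#' length increment drops fastest, r = 0.01), (2) refined by a
#' Levenberg-Marquardt least-squares fit of the biphasic curve to that
#' group's data; the group values are then mapped to the coefficient basis
#' of `spec` by group-size-weighted least squares.
#'
#' @inheritParams fit_growth
#' @return Numeric vector of fixed-coefficient starting values in
#'   [build_design()] order.
#' @export
growth_start_values <- function(tbl, spec, c = 0.15, L0 = 4.0,
                                ap = allometry_params()) {
  tbl <- treatment_factors(tbl)
  gf <- unique(tbl[, c("line", "food")])
  gf <- gf[order(gf$line, gf$food), , drop = FALSE]
  vals <- matrix(NA_real_, nrow(gf), 3,
                 dimnames = list(NULL, c("a_mat", "r", "beta")))
  wts <- numeric(nrow(gf))
  for (i in seq_len(nrow(gf))) {
    d <- tbl[tbl$line == gf$line[i] & tbl$food == gf$food[i], , drop = FALSE]
    wts[i] <- length(unique(d$fish_id))
    agg <- stats::aggregate(length ~ age, data = d, FUN = mean)
    agg <- agg[order(agg$age), ]
    beta0 <- 0.6; a_mat0 <- 60
    if (nrow(agg) >= 4) {
      W <- ap$b * agg$length^ap$alpha
      dW <- diff(W) / diff(agg$age)
      Wmid <- (W[-1] + W[-nrow(agg)]) / 2
      juv <- seq_len(max(2, floor(length(dW) / 2)))
      ok <- juv[dW[juv] > 0]
      if (length(ok) >= 2)
        beta0 <- stats::coef(stats::lm(log(dW[ok]) ~ log(Wmid[ok])))[2]
      inc <- diff(agg$length) / diff(agg$age)
      if (length(inc) >= 3) {
        drop_at <- which.min(diff(inc)) + 1
        a_mat0 <- agg$age[drop_at]
      }
    }
    beta0 <- min(max(beta0, 0.35), 0.85)
    a_mat0 <- min(max(a_mat0, 20), 140)
    st <- c(a_mat = a_mat0, r = 0.01, beta = unname(beta0))
    group_formula <- stats::as.formula(
      substitute(length ~ biphasic_length_v(age, a_mat, r, beta, c = CC,
                                            L0 = LL, alpha = AA, b = BB),
                 list(CC = c, LL = L0, AA = ap$alpha, BB = ap$b)),
      env = environment(biphasic_length_v))
    refined <- tryCatch({
      f <- minpack.lm::nlsLM(
        group_formula,
        data = d, start = as.list(st),
        lower = c(a_mat = 15, r = 1e-5, beta = 0.25),
        upper = c(a_mat = 170, r = 0.2, beta = 0.95),
        control = minpack.lm::nls.lm.control(maxiter = 100))
      stats::coef(f)
    }, error = function(e) st)
    vals[i, ] <- refined[c("a_mat", "r", "beta")]
  }
  start <- numeric(0)
  for (p in c("a_mat", "r", "beta")) {
    X <- stats::model.matrix(spec[[p]], gf)
    cf <- stats::lm.wfit(X, vals[, p], w = wts)$coefficients
    cf[is.na(cf)] <- 0
    start <- c(start, cf)
  }
  unname(start)
}

#' All candidate fixed-effect structures
#'
#' The full lattice: each of `a_mat`, `r`, `beta` independently takes one of
#' `~1`, `~line`, `~food`, `~line + food`, `~line * food` (125 specs).
#'
#' @return List of [growth_spec()] objects.
#' @export
growth_spec_lattice <- function() {
  forms <- list(~1, ~line, ~food, ~ line + food, ~ line * food)
  out <- list()
  for (fa in forms) for (fr in forms) for (fb in forms)
    out[[length(out) + 1]] <- growth_spec(a_mat = fa, r = fr, beta = fb)
  out
}

spec_label <- function(spec) {
  paste(vapply(names(spec), function(p)
    paste0(p, gsub(" ", "", paste(deparse(spec[[p]]), collapse = ""))),
    character(1)), collapse = " | ")
}

#' AIC selection over candidate fixed-effect structures
#'
#' Fits every candidate (ML) and returns the minimum-AIC fit; failed fits
#' are recorded with infinite AIC. Ties (delta AIC < 1e-6) are broken
#' towards fewer parameters, then towards the earlier candidate.
#'
#' @inheritParams fit_growth
#' @param candidate_specs List of [growth_spec()] objects.
#' @param ... Passed on to [fit_growth()].
#' @return List with `best` (a `growth_fit`) and `table` (candidate label,
#'   number of parameters, AIC, delta AIC), ordered by AIC.
#' @export
aic_select <- function(tbl, candidate_specs, random_spec = growth_random_spec("beta"),
                       ...) {
  stopifnot(length(candidate_specs) >= 1)
  fits <- vector("list", length(candidate_specs))
  aics <- rep(Inf, length(candidate_specs))
  ks <- rep(NA_real_, length(candidate_specs))
  for (i in seq_along(candidate_specs)) {
    fits[[i]] <- tryCatch(
      fit_growth(tbl, candidate_specs[[i]], random_spec, ...),
      error = function(e) NULL)
    if (!is.null(fits[[i]])) {
      aics[i] <- fits[[i]]$AIC
      ks[i] <- fits[[i]]$n_params
    }
  }
  ord <- order(aics, ks, seq_along(aics))
  best_i <- ord[1]
  near <- which(is.finite(aics) & aics - aics[best_i] < 1e-6)
  if (length(near) > 1) best_i <- near[order(ks[near], near)][1]
  tab <- data.frame(
    candidate = vapply(candidate_specs, spec_label, character(1)),
    k = ks, AIC = aics, delta_AIC = aics - aics[best_i],
    stringsAsFactors = FALSE)
  list(best = fits[[best_i]], table = tab[order(tab$AIC), ])
}

# term labels per parameter, and coefficient-name -> (param, term) mapping
coef_term_map <- function(spec, coef_names) {
  out <- data.frame(coef = coef_names, param = NA_character_,
                    term = NA_character_, stringsAsFactors = FALSE)
  for (p in names(spec)) {
    X <- stats::model.matrix(spec[[p]], data.frame(
      line = factor(c("large_selected", "small_selected"),
                    levels = c("large_selected", "small_selected")),
      food = factor(c("high", "low"), levels = c("high", "low"))))
    asg <- attr(X, "assign")
    tl <- attr(stats::terms(spec[[p]]), "term.labels")
    cn <- paste(p, colnames(X), sep = ".")
    for (j in seq_along(cn)) {
      k <- match(cn[j], out$coef)
      if (!is.na(k)) {
        out$param[k] <- p
        out$term[k] <- if (asg[j] == 0) "(Intercept)" else tl[asg[j]]
      }
    }
  }
  out
}

#' Backward elimination of non-significant treatment effects
#'
#' Iteratively removes the non-significant (p >= `alpha_level`) term with
#' the largest p-value, respecting marginality (an interaction is removed
#' before its main effects), refitting after each removal, until every
#' remaining treatment term is significant. Intercepts are never removed.
#' This mirrors the published simplification of the male model after AIC
#' ranking.
#'
#' @param fit A `growth_fit`.
#' @param alpha_level Significance threshold (default 0.05).
#' @return A `growth_fit` for the simplified model (the input fit if nothing
#'   is removable).
#' @export
backward_eliminate <- function(fit, alpha_level = 0.05) {
  stopifnot(inherits(fit, "growth_fit"))
  repeat {
    spec <- fit$spec
    ct <- fit$coef_table
    map <- coef_term_map(spec, ct$term)
    cand <- map$term != "(Intercept)"
    # marginality: a main effect is protected while its interaction remains
    for (p in names(spec)) {
      tl <- attr(stats::terms(spec[[p]]), "term.labels")
      if ("line:food" %in% tl)
        cand[map$param == p & map$term %in% c("line", "food")] <- FALSE
    }
    cand <- cand & ct$p >= alpha_level
    if (!any(cand, na.rm = TRUE)) return(fit)
    worst <- which(cand)[which.max(ct$p[cand])]
    p_drop <- map$param[worst]; t_drop <- map$term[worst]
    tl <- setdiff(attr(stats::terms(spec[[p_drop]]), "term.labels"), t_drop)
    new_form <- if (length(tl)) stats::reformulate(tl) else ~1
    args <- list(a_mat = spec$a_mat, r = spec$r, beta = spec$beta)
    args[[p_drop]] <- new_form
    new_spec <- do.call(growth_spec, args)
    fit <- fit_growth(fit$data, new_spec, fit$random_spec,
                      c = fit$constants$c, L0 = fit$constants$L0,
                      ap = allometry_params(fit$constants$alpha, fit$constants$b),
                      use_ma2 = fit$use_ma2)
  }
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Biphasic growth model fit (", x$n_fish, " fish, ", x$n_obs,
      " observations)\n", sep = "")
  cat("Fixed-effect structure:", spec_label(x$spec), "\n")
  cat("Random effects on:",
      if (length(x$random_spec)) paste(unclass(x$random_spec), collapse = ", ")
      else "none", "\n")
  cat(sprintf("logLik %.2f  AIC %.2f  sigma %.3f  MA theta (%.3f, %.3f)\n",
              x$logLik, x$AIC, x$sigma, x$theta[1], x$theta[2]))
  if (length(x$re_sd))
    cat("Random-effect SDs:",
        paste(sprintf("%s %.4g", names(x$re_sd), x$re_sd), collapse = ", "), "\n")
  cat("\nCoefficients:\n")
  print(x$coef_table, digits = 4, row.names = FALSE)
  cat("\nPer-group parameters:\n")
  print(x$group_params, digits = 4, row.names = FALSE)
  invisible(x)
}
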