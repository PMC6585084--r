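#' Zero-inflated negative binomial probability mass function
#'
#' Mixture of a point mass at zero (probability `pi0`) and an NB2 negative
#' binomial (mean `mu`, dispersion `k`; variance mu + mu^2/k):
#' P(0) = pi0 + (1 - pi0) NB(0; mu, k), P(y > 0) = (1 - pi0) NB(y; mu, k).
#'
#' @param y Non-negative integer count (vectorised).
#' @param mu Count-part mean, > 0.
#' @param k Dispersion (NB size), > 0; the Poisson limit is k -> Inf.
#' @param pi0 Zero-inflation probability, in \[0, 1).
#' @param log Return log-probability.
#' @return Probability (or log-probability) of `y`.
#' @export
zinb_pmf <- function(y, mu, k, pi0, log = FALSE) {
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(k <= 0)) stop("k must be positive")
  if (any(pi0 < 0 | pi0 >= 1)) stop("pi0 must lie in [0, 1)")
  if (any(y < 0) || any(y != floor(y))) stop("y must be a non-negative integer")
  p <- (1 - pi0) * stats::dnbinom(y, size = k, mu = mu)
  p <- ifelse(y == 0, pi0 + p, p)
  if (log) base::log(p) else p
}

behavior_checks <- function(tbl, response) {
  for (col in c("fish_id", "line", "food", "condition", "replicate", response))
    if (!col %in% names(tbl)) stop("behaviour table lacks column '", col, "'")
  if (nrow(tbl) == 0) stop("behaviour table is empty")
  y <- tbl[[response]]
  if (any(y < 0) || any(y != floor(y))) stop("counts must be non-negative integers")
  if (all(y == 0)) stop("degenerate input: response '", response, "' is all zeros")
  invisible(TRUE)
}

#' Fit a zero-inflated negative binomial mixed model
#'
#' Count part: log link, treatment fixed effects plus Gaussian random
#' intercepts for fish identity, replicate test session nested within fish,
#' and experimental condition. Zero part: logit link with treatment fixed
#' effects only. Family NB2, estimated by maximum (Laplace-approximate)
#' likelihood via [glmmTMB::glmmTMB()].
#'
#' @param tbl Behaviour table: `fish_id`, `line`, `food`, `condition`,
#'   `replicate`, and the response column.
#' @param response `"bites"` or `"freeze_s"`.
#' @param count_spec One-sided formula of treatment terms for the count
#'   part (terms from `line`, `food`, `line:food`).
#' @param zero_spec Likewise for the zero-inflation part.
#' @param re Random intercepts to include (count part), subset of
#'   `c("fish", "meas", "cond")`.
#' @return Object of class `zinb_fit`: `count_coefs` and `zero_coefs`
#'   tables (`term`, `estimate`, `se`, `z`, `p`), dispersion `k`, `re_sd`,
#'   `logLik`, `AIC`, `n_params`, `mu_bar` (mean fitted count-part mean),
#'   `converged`, plus the glmmTMB fit. Count-part contrasts exponentiate
#'   to response-scale ratios; zero-part contrasts to odds ratios.
#' @export
fit_zinb <- function(tbl, response = c("bites", "freeze_s"),
                     count_spec = ~ line * food, zero_spec = ~ line * food,
                     re = c("fish", "meas", "cond")) {
  response <- match.arg(response)
  behavior_checks(tbl, response)
  re <- match.arg(re, several.ok = TRUE)
  tbl <- treatment_factors(tbl)
  tbl$fish_id <- factor(tbl$fish_id)
  tbl$meas_id <- interaction(tbl$fish_id, tbl$replicate, drop = TRUE)
  tbl$condition <- factor(tbl$condition)
  re_terms <- c(fish = "(1 | fish_id)", meas = "(1 | meas_id)",
                cond = "(1 | condition)")[re]
  rhs <- paste(c(attr(stats::terms(count_spec), "term.labels"), "1"),
               collapse = " + ")
  form <- stats::as.formula(
    paste(response, "~", rhs, "+", paste(re_terms, collapse = " + ")))
  fit <- glmmTMB::glmmTMB(form, ziformula = zero_spec, data = tbl,
                          family = glmmTMB::nbinom2())
  sm <- summary(fit)
  mk_table <- function(m) {
    if (is.null(m) || nrow(m) == 0)
      return(data.frame(term = character(0), estimate = numeric(0),
                        se = numeric(0), z = numeric(0), p = numeric(0)))
    data.frame(term = rownames(m), estimate = m[, 1], se = m[, 2], z = m[, 3],
               p = m[, 4], row.names = NULL, stringsAsFactors = FALSE)
  }
  vc <- glmmTMB::VarCorr(fit)$cond
  re_sd <- vapply(vc, function(v) sqrt(v[1, 1]), numeric(1))
  names(re_sd) <- sub("fish_id", "fish", sub("meas_id", "meas",
                  sub("condition", "cond", names(re_sd))))
  ll <- stats::logLik(fit)
  pdh <- fit$sdr$pdHess
  structure(list(
    response = response,
    count_coefs = mk_table(sm$coefficients$cond),
    zero_coefs = mk_table(sm$coefficients$zi),
    k = glmmTMB::sigma(fit),
    re_sd = re_sd,
    logLik = as.numeric(ll),
    AIC = stats::AIC(fit),
    n_params = attr(ll, "df"),
    mu_bar = mean(stats::predict(fit, type = "conditional")),
    count_spec = count_spec,
    zero_spec = zero_spec,
    converged = isTRUE(fit$fit$convergence == 0) && isTRUE(pdh),
    boundary = any(re_sd < 1e-4),
    n_obs = nrow(tbl),
    n_fish = length(unique(tbl$fish_id)),
    data = tbl,
    fit = fit
  ), class = "zinb_fit")
}

#' @export
print.zinb_fit <- function(x, ...) {
  cat("Zero-inflated NB mixed model for", x$response,
      sprintf("(%d fish, %d observations)\n", x$n_fish, x$n_obs))
  cat(sprintf("logLik %.2f  AIC %.2f  dispersion k %.3f\n",
              x$logLik, x$AIC, x$k))
  cat("Random-intercept SDs:",
      paste(sprintf("%s %.3f", names(x$re_sd), x$re_sd), collapse = ", "), "\n")
  cat("\nCount part (log link):\n")
  print(x$count_coefs, digits = 4, row.names = FALSE)
  cat("\nZero part (logit link; exp(estimate) = odds ratio):\n")
  print(x$zero_coefs, digits = 4, row.names = FALSE)
  invisible(x)
}

#' AIC selection over ZINB fixed-effect structures
#'
#' @inheritParams fit_zinb
#' @param candidates List of `list(count = ~..., zero = ~...)` candidate
#'   structures (see [zinb_spec_lattice()]).
#' @param ... Passed to [fit_zinb()].
#' @return List with `best` (`zinb_fit`) and `table` (ordered by AIC);
#'   failed fits carry infinite AIC, ties break to fewer parameters.
#' @export
aic_select_zinb <- function(tbl, response, candidates, ...) {
  stopifnot(length(candidates) >= 1)
  fits <- vector("list", length(candidates))
  aics <- rep(Inf, length(candidates))
  ks <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    fits[[i]] <- tryCatch(
      fit_zinb(tbl, response, count_spec = candidates[[i]]$count,
               zero_spec = candidates[[i]]$zero, ...),
      error = function(e) NULL)
    if (!is.null(fits[[i]]) && is.finite(fits[[i]]$AIC)) {
      aics[i] <- fits[[i]]$AIC
      ks[i] <- fits[[i]]$n_params
    }
  }
  best_i <- order(aics, ks, seq_along(aics))[1]
  near <- which(is.finite(aics) & aics - aics[best_i] < 1e-6)
  if (length(near) > 1) best_i <- near[order(ks[near], near)][1]
  lab <- function(f) gsub(" ", "", paste(deparse(f), collapse = ""))
  tab <- data.frame(
    count = vapply(candidates, function(s) lab(s$count), character(1)),
    zero = vapply(candidates, function(s) lab(s$zero), character(1)),
    k = ks, AIC = aics, delta_AIC = aics - aics[best_i],
    stringsAsFactors = FALSE)
  list(best = fits[[best_i]], table = tab[order(tab$AIC), ])
}

#' Candidate lattice for the ZINB fixed effects
#'
#' All combinations of `~1`, `~line`, `~food`, `~line + food`,
#' `~line * food` for the count and zero parts independently (25).
#'
#' @return List of `list(count, zero)` candidates.
#' @export
zinb_spec_lattice <- function() {
  forms <- list(~1, ~line, ~food, ~ line + food, ~ line * food)
  out <- list()
  for (fc in forms) for (fz in forms)
    out[[length(out) + 1]] <- list(count = fc, zero = fz)
  out
}

#' Posterior-predictive check of the zero count
#'
#' Simulates datasets from the fitted model (new residual and zero-state
#' draws, random effects conditioned on their estimates) and reports the
#' fraction of simulations whose number of zeros falls within `tol` (as a
#' proportion of observations) of the observed zero count.
#'
#' @param fit A `zinb_fit`.
#' @param n_sims Number of simulated datasets.
#' @param tol Tolerance as a proportion of the number of observations
#'   (default 0.02, i.e. within +/- 2%).
#' @return Fraction in \[0, 1\]; attribute `"zeros"` holds the simulated
#'   zero counts and the observed count.
#' @export
zero_fraction_check <- function(fit, n_sims = 200, tol = 0.02) {
  stopifnot(inherits(fit, "zinb_fit"))
  obs <- sum(fit$data[[fit$response]] == 0)
  sims <- stats::simulate(fit$fit, nsim = n_sims)
  zeros <- vapply(sims, function(y) sum(y == 0), numeric(1))
  frac <- mean(abs(zeros - obs) <= tol * fit$n_obs)
  attr(frac, "zeros") <- list(simulated = unname(zeros), observed = obs)
  frac
}

#' Latent-scale repeatability (ICC) from a fitted behaviour model
#'
#' Variance-partition repeatability of the count part on the latent log
#' scale: fish-level variance divided by the sum of the fish, session
#' (measurement-within-fish) and condition intercept variances plus the
#' distribution-level variance, the lognormal approximation
#' log(1 + 1/mu_bar + 1/k).
#'
#' @param fit A `zinb_fit`, or a list with fields `re_sd` (named numeric
#'   with some of `fish`, `meas`, `cond`), `k` and `mu_bar`.
#' @return Proportion in \[0, 1\].
#' @export
repeatability_icc <- function(fit) {
  v <- stats::setNames(fit$re_sd[c("fish", "meas", "cond")]^2,
                       c("fish", "meas", "cond"))
  v[is.na(v)] <- 0
  resid_var <- log(1 + 1 / fit$mu_bar + 1 / fit$k)
  tot <- sum(v) + resid_var
  if (tot == 0) return(0)
  unname(v["fish"] / tot)
}
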