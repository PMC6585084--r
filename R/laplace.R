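#' Laplace-approximate marginal log-likelihood of the growth model
#'
#' Evaluates, for fixed coefficient values, the marginal likelihood of a
#' trajectory table under the biphasic model with individual Gaussian random
#' effects (natural scale, on the parameters named in `random_sd`) and an
#' MA(2) residual covariance. Per fish, the random effects are integrated
#' out by a Laplace approximation at the per-fish conditional mode (found by
#' quasi-Newton search); with all random-effect SDs zero the expression
#' reduces exactly to the independent-observation (or MA(2)-correlated)
#' Gaussian nonlinear-regression log-likelihood. Deterministic given its
#' inputs; used for validation and diagnostics, not as the production
#' optimiser (fitting goes through [fit_growth()]).
#'
#' @param tbl Trajectory table (`fish_id`, `line`, `food`, `age`, `length`).
#' @param spec A [growth_spec()].
#' @param coefs Fixed-coefficient vector in [build_design()] order.
#' @param random_sd Named numeric: SD per random-effect-carrying parameter,
#'   e.g. `c(beta = 0.02)` or `c(r = 0.003, beta = 0.02)`. Entries equal to
#'   zero are dropped.
#' @param sigma Marginal residual SD (mm).
#' @param theta Length-2 MA coefficients (default `c(0, 0)`: diagonal
#'   covariance).
#' @param c,L0 Fixed model constants.
#' @param ap [allometry_params()].
#' @return Scalar log-likelihood. Attribute `"modes"`: per-fish random-effect
#'   modes (matrix), when random effects are present.
#' @export
marginal_loglik <- function(tbl, spec, coefs, random_sd = numeric(0),
                            sigma, theta = c(0, 0),
                            c = 0.15, L0 = 4.0, ap = allometry_params()) {
  stopifnot(sigma > 0, length(theta) == 2)
  tbl <- treatment_factors(tbl)
  tbl <- tbl[order(tbl$fish_id, tbl$age), , drop = FALSE]
  design <- build_design(tbl, spec)
  pv <- design_param_values(design, coefs)
  fish_ids <- design$fish$fish_id
  random_sd <- random_sd[random_sd > 0]
  rp <- names(random_sd)
  stopifnot(all(rp %in% c("a_mat", "r", "beta")))
  q <- length(rp)

  # precompute covariance solves per distinct series length
  Vcache <- new.env(parent = emptyenv())
  get_V <- function(n) {
    key <- as.character(n)
    if (is.null(Vcache[[key]])) {
      V <- ma2_covariance(sigma, theta[1], theta[2], n)
      ch <- chol(V)
      Vcache[[key]] <- list(chol = ch, ldet = 2 * sum(log(diag(ch))))
    }
    Vcache[[key]]
  }

  ll <- 0
  modes <- if (q) matrix(0, length(fish_ids), q, dimnames = list(NULL, rp))
  for (i in seq_along(fish_ids)) {
    d <- tbl[tbl$fish_id == fish_ids[i], , drop = FALSE]
    n <- nrow(d)
    Vi <- get_V(n)
    pars <- c(a_mat = pv$a_mat[i], r = pv$r[i], beta = pv$beta[i])
    resid_quad <- function(u) {
      p <- pars
      p[rp] <- p[rp] + u
      p["r"] <- max(p["r"], 0)
      mu <- biphasic_length_v(d$age, p["a_mat"], p["r"], p["beta"],
                              c = c, L0 = L0, alpha = ap$alpha, b = ap$b)
      z <- backsolve(Vi$chol, d$length - mu, transpose = TRUE)
      sum(z^2)
    }
    if (q == 0) {
      ll <- ll + (-0.5 * (n * log(2 * pi) + Vi$ldet + resid_quad(numeric(0))))
      next
    }
    g <- function(u) 0.5 * resid_quad(u) + 0.5 * sum(u^2 / random_sd^2)
    # keep the perturbed parameters inside their domains during the search
    lower <- vapply(rp, function(p) switch(p,
      beta = 0.01 - pars["beta"], r = -pars["r"], a_mat = 1 - pars["a_mat"]),
      numeric(1))
    upper <- vapply(rp, function(p) switch(p,
      beta = 0.99 - pars["beta"], r = Inf, a_mat = Inf), numeric(1))
    opt <- stats::nlminb(rep(0, q), g, lower = lower, upper = upper)
    if (opt$convergence != 0 && opt$objective > g(rep(0, q)))
      stop("inner mode search failed for fish ", fish_ids[i])
    u_hat <- opt$par
    modes[i, ] <- u_hat
    Hg <- numeric_hessian(g, u_hat)
    det_Hg <- det(as.matrix(Hg))
    if (!is.finite(det_Hg) || det_Hg <= 0)
      stop("non-positive curvature at inner mode for fish ", fish_ids[i])
    ll <- ll + (-0.5 * (n * log(2 * pi) + Vi$ldet) -
                  sum(log(random_sd)) - g(u_hat) - 0.5 * log(det_Hg))
  }
  if (q) attr(ll, "modes") <- modes
  ll
}

# central finite-difference Hessian for small q
numeric_hessian <- function(f, x, h = 1e-4) {
  q <- length(x)
  H <- matrix(0, q, q)
  for (i in seq_len(q)) {
    ei <- replace(numeric(q), i, h)
    for (j in i:q) {
      ej <- replace(numeric(q), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}
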