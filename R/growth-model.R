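#' Quince-Boukal biphasic growth model
#'
#' Closed-form length-at-age under a biphasic energy-allocation model:
#' juveniles put all surplus energy into somatic growth, which scales
#' allometrically with weight (dW/dt = c W^beta); after maturation a
#' constant fraction of surplus energy is diverted to reproduction, which
#' discounts adult growth by the per-day factor R = 1 / (1 + (1 - beta) r).
#' The juvenile and adult curves join continuously at the age at maturation.
#'
#' Lengths are in mm, weights in mg, ages in days post-hatch (dph).
#'
#' @name biphasic-model
NULL

#' Construct growth parameters
#'
#' @param a_mat Age at maturation (dph), > 0.
#' @param r Reproductive investment rate per day, >= 0.
#' @param beta Allometric exponent of maximal potential growth, in (0, 1).
#' @param c Coefficient of the growth-rate allometry dW/dt = c W^beta, in
#'   mg^(1-beta) day^-1. Fixed at 0.15 for medaka.
#' @param L0 Length at hatch (mm), > 0.
#' @return An object of class `growth_params`. The somatic-gonadic
#'   conversion factor q is fixed at 1 and not exposed.
#' @export
growth_params <- function(a_mat, r, beta, c = 0.15, L0 = 4.0) {
  stopifnot(is.numeric(a_mat), is.numeric(r), is.numeric(beta))
  if (any(a_mat <= 0)) stop("a_mat must be positive")
  if (any(r < 0)) stop("r must be non-negative")
  if (any(beta <= 0 | beta >= 1)) stop("beta must lie in (0, 1)")
  if (any(c <= 0)) stop("c must be positive")
  if (any(L0 <= 0)) stop("L0 must be positive")
  structure(list(a_mat = a_mat, r = r, beta = beta, c = c, L0 = L0),
            class = "growth_params")
}

#' Construct weight-length allometry parameters
#'
#' The allometry W = b L^alpha links weight (mg) to standard length (mm).
#'
#' @param alpha Dimensionless exponent, > 0.
#' @param b Coefficient in mg mm^(-alpha), > 0.
#' @return An object of class `allometry_params`.
#' @export
allometry_params <- function(alpha = 2.7, b = 0.04) {
  if (any(alpha <= 0)) stop("alpha must be positive")
  if (any(b <= 0)) stop("b must be positive")
  structure(list(alpha = alpha, b = b), class = "allometry_params")
}

#' Composite growth constants H and R
#'
#' H = c (1 - beta) b^-(1 - beta) collects the growth-rate and weight-length
#' allometries into a single constant on the transformed length scale
#' L^((1-beta) alpha); R = 1 / (1 + (1 - beta) r) is the per-day discount
#' applied to adult growth by reproductive investment (R = 1 iff r = 0).
#'
#' @param gp A [growth_params()] object.
#' @param ap An [allometry_params()] object.
#' @return List with elements `H` (> 0) and `R` (in (0, 1]).
#' @export
derived_constants <- function(gp, ap) {
  if (any(gp$beta >= 1)) stop("beta must be < 1: exponent 1 - beta must be positive")
  omb <- 1 - gp$beta
  H <- gp$c * omb * ap$b^(-omb)
  R <- 1 / (1 + omb * gp$r)
  list(H = H, R = R)
}

#' Juvenile length at age
#'
#' Closed-form solution of dW/dt = c W^beta under W = b L^alpha:
#' L_a = (L0^((1-beta) alpha) + H a)^(1 / ((1-beta) alpha)).
#'
#' @param a Age in dph, >= 0 (vectorised).
#' @inheritParams derived_constants
#' @return Length in mm.
#' @export
juvenile_length <- function(a, gp, ap) {
  if (any(a < 0)) stop("age must be non-negative")
  k <- (1 - gp$beta) * ap$alpha
  H <- derived_constants(gp, ap)$H
  (gp$L0^k + H * a)^(1 / k)
}

#' Adult length at age
#'
#' Implements the reproduction-discounted adult phase,
#' L_a = (R^(a - a_mat) (L0^k + H a_mat) + R H / (1 - R) (1 - R^(a - a_mat)))^(1/k)
#' with k = (1-beta) alpha. For r = 0 (R = 1) the geometric-sum limit
#' (1 - R^d) / (1 - R) -> d is taken analytically, recovering the juvenile
#' curve; as a -> Inf length approaches (R H / (1 - R))^(1/k) =
#' (c b^-(1-beta) / r)^(1/k).
#'
#' @param a Age in dph, >= a_mat (vectorised).
#' @inheritParams derived_constants
#' @return Length in mm.
#' @export
adult_length <- function(a, gp, ap) {
  if (any(a < gp$a_mat)) stop("adult_length requires a >= a_mat")
  k <- (1 - gp$beta) * ap$alpha
  dc <- derived_constants(gp, ap)
  H <- dc$H; R <- dc$R
  d <- a - gp$a_mat
  x_mat <- gp$L0^k + H * gp$a_mat
  if (1 - R < 1e-12) {
    # analytic r -> 0 limit: R^d (...) + H d
    x <- x_mat + H * d
  } else {
    x <- R^d * x_mat + R * H / (1 - R) * (1 - R^d)
  }
  x^(1 / k)
}

#' Biphasic length at age
#'
#' Piecewise dispatch: juvenile curve up to a_mat, adult curve beyond.
#' Continuous and non-decreasing in age for r >= 0.
#'
#' @param a Age in dph, >= 0 (vectorised).
#' @inheritParams derived_constants
#' @return Length in mm.
#' @export
biphasic_length <- function(a, gp, ap) {
  if (any(a < 0)) stop("age must be non-negative")
  out <- numeric(length(a))
  juv <- a <= gp$a_mat
  if (any(juv)) out[juv] <- juvenile_length(a[juv], gp, ap)
  if (any(!juv)) out[!juv] <- adult_length(a[!juv], gp, ap)
  out
}

#' Asymptotic adult length
#'
#' Limit of [adult_length()] as age grows without bound,
#' (R H / (1 - R))^(1 / ((1-beta) alpha)); infinite when r = 0.
#'
#' @inheritParams derived_constants
#' @return Length in mm (possibly `Inf`).
#' @export
asymptotic_length <- function(gp, ap) {
  k <- (1 - gp$beta) * ap$alpha
  dc <- derived_constants(gp, ap)
  if (1 - dc$R < 1e-12) return(Inf)
  (dc$R * dc$H / (1 - dc$R))^(1 / k)
}

#' Weight from length and back
#'
#' @param L Length in mm, > 0.
#' @param ap An [allometry_params()] object.
#' @return Weight in mg.
#' @export
weight_from_length <- function(L, ap) {
  if (any(L <= 0)) stop("length must be positive")
  ap$b * L^ap$alpha
}

#' @param W Weight in mg, > 0.
#' @rdname weight_from_length
#' @export
length_from_weight <- function(W, ap) {
  if (any(W <= 0)) stop("weight must be positive")
  (W / ap$b)^(1 / ap$alpha)
}

#' Vectorised biphasic curve over per-observation parameters
#'
#' Evaluates the biphasic length-at-age curve where `a_mat`, `r` and `beta`
#' may vary observation by observation (recycled to the length of `a`); this
#' is the model function the nonlinear mixed-effects fit maximises over.
#' Negative ages are not rejected here (the optimiser never produces them);
#' use [biphasic_length()] for the checked scalar-parameter interface.
#'
#' @param a Ages in dph.
#' @param a_mat,r,beta Growth parameters, each scalar or per-observation.
#' @param c,L0,alpha,b Fixed constants of the growth and weight-length
#'   allometries.
#' @return Lengths in mm.
#' @export
biphasic_length_v <- function(a, a_mat, r, beta, c = 0.15, L0 = 4.0,
                              alpha = 2.7, b = 0.04) {
  n <- length(a)
  a_mat <- rep_len(a_mat, n); r <- rep_len(r, n); beta <- rep_len(beta, n)
  omb <- 1 - beta
  k <- omb * alpha
  H <- c * omb * b^(-omb)
  R <- 1 / (1 + omb * r)
  x_juv <- L0^k + H * a
  d <- pmax(a - a_mat, 0)
  x_mat <- L0^k + H * a_mat
  one_m_R <- omb * r / (1 + omb * r)
  x_ad <- ifelse(one_m_R < 1e-12,
                 x_mat + H * d,
                 R^d * x_mat + R * H / (1 - R) * (1 - R^d))
  x <- ifelse(a <= a_mat, x_juv, x_ad)
  x^(1 / k)
}
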