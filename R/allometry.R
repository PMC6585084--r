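#' Estimate the weight-length allometry
#'
#' Ordinary least squares of log(weight) on log(length), pooled across sexes
#' and treatments; run on the raw data before the growth model so that the
#' allometry (alpha, b) can be held fixed during the nonlinear fit.
#' No retransformation bias correction is applied to b = exp(intercept).
#'
#' @param tbl Trajectory table (see [generate_growth()]) with columns
#'   `length` (mm) and `weight` (mg); rows with missing weight are dropped.
#' @return An [allometry_params()] object with the fitted `alpha` (slope) and
#'   `b` (exp intercept), carrying the `lm` fit in attribute `"fit"`.
#' @export
fit_allometry <- function(tbl) {
  stopifnot(is.data.frame(tbl), all(c("length", "weight") %in% names(tbl)))
  ok <- stats::complete.cases(tbl$length, tbl$weight)
  d <- tbl[ok, , drop = FALSE]
  if (nrow(d) < 10) stop("need at least 10 rows with both length and weight")
  if (any(d$length <= 0) || any(d$weight <= 0))
    stop("lengths and weights must be positive for the log-log regression")
  fit <- stats::lm(log(weight) ~ log(length), data = d)
  cf <- stats::coef(fit)
  ap <- allometry_params(alpha = unname(cf[2]), b = exp(unname(cf[1])))
  attr(ap, "fit") <- fit
  ap
}

#' Estimate hatch length and test for sex/line differences
#'
#' Pools per-fish lengths measured at 0 dph and reports the mean together
#' with one-way F-tests for a sex and a line effect (each with 1 numerator
#' df). The growth model uses a fixed hatch length; the pipeline default is
#' 4.0 mm, set in configuration rather than taken verbatim from this mean.
#'
#' @param hatch Data frame with columns `length` (mm at 0 dph), `sex`, `line`.
#' @return List with `L0` (pooled mean, mm), `L0_rounded` (one decimal),
#'   `sd`, `n`, and `sex_test` / `line_test` (each `F`, `df1`, `df2`, `p`).
#' @export
estimate_L0 <- function(hatch) {
  stopifnot(is.data.frame(hatch), all(c("length", "sex", "line") %in% names(hatch)))
  if (nrow(hatch) < 6 || any(table(hatch$sex) < 3) || any(table(hatch$line) < 3))
    stop("need at least 3 fish per sex and per line")
  one_way <- function(f) {
    a <- suppressWarnings(
      stats::anova(stats::lm(length ~ g,
                             data = data.frame(length = hatch$length, g = f))))
    Fv <- a$`F value`[1]; p <- a$`Pr(>F)`[1]
    if (a$`Sum Sq`[1] < 1e-12) { # degenerate: no between-group variation
      Fv <- 0; p <- 1
    }
    list(F = Fv, df1 = a$Df[1], df2 = a$Df[2], p = p)
  }
  list(L0 = mean(hatch$length),
       L0_rounded = round(mean(hatch$length), 1),
       sd = stats::sd(hatch$length),
       n = nrow(hatch),
       sex_test = one_way(factor(hatch$sex)),
       line_test = one_way(factor(hatch$line)))
}
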