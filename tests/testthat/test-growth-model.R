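test_that("derived constants H and R follow their defining formulas", {
  ap <- ap_default()
  # zero investment leaves no reproduction discount
  dc0 <- derived_constants(growth_params(48, 0, 0.66), ap)
  expect_identical(dc0$R, 1)
  # direct arithmetic on the published female high-food values
  dc <- derived_constants(gp_female_high(), ap)
  expect_equal(dc$R, 1 / (1 + 0.34 * 0.018), tolerance = 1e-12)
  expect_equal(dc$H, 0.15 * 0.34 * 0.04^(-0.34), tolerance = 1e-12)
  expect_error(derived_constants(
    structure(list(a_mat = 48, r = 0.01, beta = 1.2, c = 0.15, L0 = 4),
              class = "growth_params"), ap), "beta")
})

test_that("juvenile closed form starts at L0, grows with H, matches the ODE", {
  gp <- gp_female_high(); ap <- ap_default()
  expect_equal(juvenile_length(0, gp, ap), gp$L0, tolerance = 1e-12)
  expect_error(juvenile_length(-1, gp, ap), "non-negative")

  # doubling H (via c) strictly increases length at every positive age
  gp2 <- growth_params(48, 0.018, 0.66, c = 0.30)
  a <- seq(1, 180, by = 1)
  expect_true(all(juvenile_length(a, gp2, ap) > juvenile_length(a, gp, ap)))

  # oracle: numerical integration of dW/dt = c W^beta, converted via W = b L^alpha
  skip_if_not_installed("deSolve")
  ode <- deSolve::ode(
    y = c(W = ap$b * gp$L0^ap$alpha),
    times = seq(0, 180, by = 2),
    func = function(t, y, p) list(gp$c * y^gp$beta), parms = NULL,
    method = "ode45", atol = 1e-10, rtol = 1e-10)
  L_ode <- (ode[, "W"] / ap$b)^(1 / ap$alpha)
  expect_equal(juvenile_length(ode[, "time"], gp, ap), unname(L_ode),
               tolerance = 1e-6)
})

test_that("adult curve joins the juvenile curve continuously at maturation", {
  ap <- ap_default()
  ps <- random_growth_params(1000)
  gap <- vapply(seq_len(nrow(ps)), function(i) {
    gp <- growth_params(ps$a_mat[i], ps$r[i], ps$beta[i], ps$c[i], ps$L0[i])
    api <- allometry_params(ps$alpha[i], ps$b[i])
    abs(juvenile_length(gp$a_mat, gp, api) - adult_length(gp$a_mat, gp, api))
  }, numeric(1))
  expect_lt(max(gap), 1e-10)
})

test_that("zero-investment limit of the adult curve is the juvenile curve", {
  ap <- ap_default()
  gp <- growth_params(48, 1e-12, 0.66)
  a <- seq(48, 180, by = 1)
  expect_lt(max(abs(adult_length(a, gp, ap) - juvenile_length(a, gp, ap))), 1e-6)
  expect_error(adult_length(40, gp, ap), "a_mat")
})

test_that("adult curve matches the step-wise allocation recursion and its asymptote", {
  ap <- ap_default()
  gp <- gp_female_low_large() # a_mat = 97, r = 0.007, beta = 0.53
  dc <- derived_constants(gp, ap)
  k <- (1 - gp$beta) * ap$alpha
  # forward recursion on the transformed scale: x_{a+1} = R (x_a + H)
  x <- gp$L0^k + dc$H * gp$a_mat
  for (a in seq(gp$a_mat, 179)) x <- dc$R * (x + dc$H)
  expect_equal(adult_length(180, gp, ap), x^(1 / k), tolerance = 1e-10)

  # asymptote in both algebraic forms, numerically at a = 1e5 days
  asym <- asymptotic_length(gp, ap)
  expect_equal(asym, (gp$c * ap$b^(-(1 - gp$beta)) / gp$r)^(1 / k),
               tolerance = 1e-12)
  expect_equal(adult_length(1e5, gp, ap), asym, tolerance = 1e-8)
  expect_identical(asymptotic_length(growth_params(48, 0, 0.66), ap), Inf)
})

test_that("biphasic trajectory is continuous, monotone, and ordered by food", {
  ap <- ap_default()
  # whole trajectory at r = 0 equals the juvenile curve
  gp0 <- growth_params(48, 0, 0.66)
  a <- seq(0, 365, by = 0.5)
  expect_equal(biphasic_length(a, gp0, ap), juvenile_length(a, gp0, ap),
               tolerance = 1e-12)
  # monotone non-decreasing in age over [0, 365] at every published
  # parameter combination (maturation length below the adult asymptote)
  published <- rbind(
    c(48, 0.018, 0.66), c(97, 0.007, 0.53), c(81, 0.007, 0.53),
    c(63, 0.016, 0.63), c(63, 0.016, 0.61), c(78, 0.008, 0.53),
    c(78, 0.008, 0.52))
  for (i in seq_len(nrow(published))) {
    gp <- growth_params(published[i, 1], published[i, 2], published[i, 3])
    L <- biphasic_length(a, gp, ap)
    expect_true(all(diff(L) >= -1e-12))
    expect_true(all(L <= asymptotic_length(gp, ap)))
  }
  # high-food female curve dominates the low-food curve at every age
  hi <- biphasic_length(0:180, gp_female_high(), ap)
  lo <- biphasic_length(0:180, gp_female_low_large(), ap)
  expect_true(all(hi >= lo - 1e-12)) # equal at hatch, dominated after
})

test_that("growth slows at maturation when investment is positive", {
  ap <- ap_default()
  gp <- gp_female_high()
  h <- 1e-3
  slope_below <- (biphasic_length(gp$a_mat - h, gp, ap) -
                  biphasic_length(gp$a_mat - 2 * h, gp, ap)) / h
  slope_above <- (biphasic_length(gp$a_mat + 2 * h, gp, ap) -
                  biphasic_length(gp$a_mat + h, gp, ap)) / h
  expect_lt(slope_above, slope_below)
})

test_that("length increases with beta over the fitted range", {
  ap <- ap_default()
  betas <- seq(0.5, 0.7, by = 0.05)
  a <- seq(14, 180, by = 7)
  L <- sapply(betas, function(bb)
    biphasic_length(a, growth_params(48, 0.018, bb), ap))
  expect_true(all(apply(L, 1, diff) > 0))
})

test_that("weight-length allometry is exact and invertible", {
  ap <- ap_default()
  expect_equal(weight_from_length(1, ap), ap$b, tolerance = 1e-15)
  expect_equal(weight_from_length(4.0, ap), 0.04 * 4^2.7, tolerance = 1e-12)
  expect_error(weight_from_length(0, ap), "positive")
  set.seed(11)
  L <- runif(100, 3, 40)
  expect_equal(length_from_weight(weight_from_length(L, ap), ap), L,
               tolerance = 1e-10)
})
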