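test_that("the zero-inflated NB pmf is a proper probability mass function", {
  # point-mass limit
  expect_equal(zinb_pmf(0, mu = 5, k = 1.2, pi0 = 1 - 1e-12), 1, tolerance = 1e-9)
  # Poisson limit at huge dispersion
  y <- 0:15
  expect_equal(zinb_pmf(y, mu = 5, k = 1e8, pi0 = 0), dpois(y, 5),
               tolerance = 1e-6)
  # normalisation over the support
  expect_equal(sum(zinb_pmf(0:1e4, mu = 5, k = 1.2, pi0 = 0.4)), 1,
               tolerance = 1e-8)
  # the zero mass splits into structural and sampling zeros
  expect_equal(zinb_pmf(0, 5, 1.2, 0.4),
               0.4 + 0.6 * dnbinom(0, size = 1.2, mu = 5), tolerance = 1e-12)
  expect_error(zinb_pmf(0, -1, 1, 0.2), "mu")
  expect_error(zinb_pmf(0, 1, 0, 0.2), "k")
  expect_error(zinb_pmf(0, 1, 1, 1.2), "pi0")
  expect_error(zinb_pmf(-2, 1, 1, 0.2), "integer")
})

test_that("ZINB mixed fit recovers structure and flags degenerate input", {
  cfg <- synth_config("F")
  b <- generate_behavior(cfg, seed = 51)
  fit <- fit_zinb(b, "bites", count_spec = ~food, zero_spec = ~ line + food)
  expect_named(fit$count_coefs, c("term", "estimate", "se", "z", "p"))
  expect_equal(nrow(fit$zero_coefs), 3)
  expect_gt(fit$k, 0)
  expect_named(fit$re_sd, c("fish", "meas", "cond"))
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$n_params, tolerance = 1e-8)
  expect_equal(fit$n_obs, 480) # 80 females x 6 observations
  expect_output(print(fit), "Zero-inflated NB mixed model")

  b0 <- b; b0$bites <- 0L
  expect_error(fit_zinb(b0, "bites"), "all zeros")
  expect_error(fit_zinb(b[, -1], "bites"), "fish_id")
})

test_that("without true zero inflation the zero part drifts to the floor", {
  cfg <- synth_config("F")
  cfg$behavior$bites$zero[] <- c(-30, 0, 0, 0) # pi ~ 0 everywhere
  b <- generate_behavior(cfg, seed = 52)
  fit <- fit_zinb(b, "bites", count_spec = ~food, zero_spec = ~1)
  expect_lt(fit$zero_coefs$estimate[1], -3) # large negative logit
  expect_equal(fit$count_coefs$estimate[1], cfg$behavior$bites$count["intercept"],
               ignore_attr = TRUE, tolerance = 0.15)
})

test_that("AIC selection over ZINB candidates behaves deterministically", {
  cfg <- synth_config("F")
  b <- generate_behavior(cfg, seed = 53)
  one <- aic_select_zinb(b, "bites",
                         list(list(count = ~food, zero = ~ line + food)))
  expect_equal(nrow(one$table), 1)
  # the published female-bites structure is representable in the lattice
  lat <- zinb_spec_lattice()
  labs <- vapply(lat, function(s)
    paste(deparse(s$count), deparse(s$zero)), character(1))
  expect_true("~food ~line + food" %in% labs)
  expect_length(lat, 25)
})

test_that("food-only truth selects food-only structures in most replicates", {
  cfg <- synth_config("F")
  # truth: food on both parts, no line anywhere
  cfg$behavior$bites$zero["line"] <- 0
  cands <- list(list(count = ~food, zero = ~food),
                list(count = ~ line + food, zero = ~ line + food))
  wins <- 0L
  n_rep <- 8
  for (s in seq_len(n_rep)) {
    b <- generate_behavior(cfg, seed = 520 + s)
    sel <- aic_select_zinb(b, "bites", cands)
    if (identical(sel$table$count[1], "~food") &&
        identical(sel$table$zero[1], "~food")) wins <- wins + 1L
  }
  expect_gt(wins, n_rep / 2)
})

test_that("posterior-predictive zero check separates good and broken models", {
  cfg <- synth_config("F")
  b <- generate_behavior(cfg, seed = 54)
  fit <- fit_zinb(b, "bites", count_spec = ~food, zero_spec = ~ line + food)
  frac <- zero_fraction_check(fit, n_sims = 200, tol = 0.02)
  expect_gt(frac, 0.2) # well-specified model reproduces its zeros often
  frac0 <- zero_fraction_check(fit, n_sims = 200, tol = 0)
  expect_gte(frac0, 0)
  expect_lte(frac0, frac)

  # model with the zero part suppressed on heavily zero-inflated data
  fit_nozi <- suppressWarnings(
    fit_zinb(b, "bites", count_spec = ~food, zero_spec = ~0))
  frac_nozi <- zero_fraction_check(fit_nozi, n_sims = 200, tol = 0.02)
  expect_lt(frac_nozi, frac)
})

test_that("latent-scale repeatability behaves at its boundaries and recovers", {
  # no fish-level variance -> 0
  f0 <- list(re_sd = c(fish = 0, meas = 0.3, cond = 0.2), k = 1.2, mu_bar = 10)
  expect_equal(repeatability_icc(f0), 0)
  # only fish-level variance, negligible distribution variance -> 1
  f1 <- list(re_sd = c(fish = 0.8, meas = 0, cond = 0), k = 1e8, mu_bar = 1e8)
  expect_equal(repeatability_icc(f1), 1, tolerance = 1e-6)

  # recovery of a designed ICC at 200 fish
  cfg <- synth_config("F")
  cfg$groups$n_behavior <- rep(50, 4)
  cfg$behavior$bites$re_sd <- c(fish = 0.5, meas = 0.3, cond = 0)
  cfg$behavior$bites$count["intercept"] <- log(50)
  cfg$behavior$bites$zero[] <- c(-30, 0, 0, 0)
  cfg$behavior$bites$k <- 15
  icc_true <- 0.25 / (0.25 + 0.09 + log(1 + 1 / 50 + 1 / 15))
  b <- generate_behavior(cfg, seed = 55)
  fit <- fit_zinb(b, "bites", count_spec = ~1, zero_spec = ~1,
                  re = c("fish", "meas"))
  expect_lt(abs(repeatability_icc(fit) - icc_true), 0.1)
})
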