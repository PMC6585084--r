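test_that("noiseless data recover the generating coefficients", {
  cfg <- synth_config("F")
  cfg$groups$n_growth <- rep(6, 4)
  cfg$sd_beta <- 0; cfg$sigma <- 1e-4 # effectively noiseless
  d <- generate_growth(cfg, seed = 21)
  fit <- fit_growth(d, default_growth_spec("F"),
                    growth_random_spec(character(0)), use_ma2 = FALSE)
  gp <- fit$group_params
  hi <- gp[gp$food == "high" & gp$line == "large_selected", ]
  expect_equal(hi$a_mat, 48, tolerance = 1e-3)
  expect_equal(hi$r, 0.018, tolerance = 1e-3)
  expect_equal(hi$beta, 0.66, tolerance = 1e-3)
  ll <- gp[gp$food == "low" & gp$line == "large_selected", ]
  expect_equal(ll$a_mat, 97, tolerance = 1e-2)
})

test_that("fixed-effects-only fit equals plain nonlinear least squares", {
  d <- tiny_trajectory(n_per_group = 5, sigma = 0.3, seed = 22)
  spec <- growth_spec(a_mat = ~food, r = ~1, beta = ~food)
  fit <- fit_growth(d, spec, growth_random_spec(character(0)), use_ma2 = FALSE,
                    control = list(tolerance = 1e-10))
  # independent route: nls on the same coefficient parameterisation
  d2 <- biphasr:::treatment_factors(d)
  d2$xlow <- as.numeric(d2$food == "low")
  nls_fit <- minpack.lm::nlsLM(
    length ~ biphasr:::biphasic_length_v(age, am0 + am1 * xlow, r0,
                                         b0 + b1 * xlow),
    data = d2,
    start = list(am0 = 50, am1 = 40, r0 = 0.01, b0 = 0.65, b1 = -0.1),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14))
  est <- fit$coef_table$estimate
  ref <- unname(coef(nls_fit))
  expect_equal(est, ref, tolerance = 1e-5)
})

test_that("AIC equals -2 logLik + 2 k for every returned fit", {
  d <- tiny_trajectory(n_per_group = 5, sigma = 0.3, seed = 23)
  for (rs in list(growth_random_spec(character(0)), growth_random_spec("beta"))) {
    fit <- fit_growth(d, growth_spec(a_mat = ~food, beta = ~food), rs)
    expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$n_params, tolerance = 1e-10)
  }
})

test_that("growth_fit reports the full published summary surface", {
  cfg <- synth_config("F")
  cfg$groups$n_growth <- rep(8, 4)
  d <- generate_growth(cfg, seed = 24)
  fit <- fit_growth(d, default_growth_spec("F"), default_growth_random_spec("F"))
  expect_named(fit$coef_table, c("term", "estimate", "se", "df", "t", "p"))
  expect_equal(nrow(fit$coef_table), 8)
  expect_equal(nrow(fit$group_params), 4)
  expect_true(all(fit$group_params$a_mat > 0))
  expect_true(all(fit$group_params$beta > 0 & fit$group_params$beta < 1))
  expect_true(all(fit$group_params$r >= 0))
  expect_named(fit$theta, c("theta1", "theta2"))
  expect_named(fit$re_sd, "beta")
  expect_true(is.finite(fit$logLik))
  expect_output(print(fit), "Biphasic growth model fit")
})

test_that("fish with fewer than four measurements are excluded", {
  d <- tiny_trajectory(n_per_group = 5, sigma = 0.3, seed = 25)
  short_id <- unique(d$fish_id)[1]
  d2 <- rbind(d[d$fish_id != short_id, ], d[d$fish_id == short_id, ][1:3, ])
  fit <- fit_growth(d2, growth_spec(beta = ~food), growth_random_spec("beta"))
  expect_equal(fit$n_fish, length(unique(d$fish_id)) - 1)
  expect_error(fit_growth(d[d$age < 70, ], growth_spec(), growth_random_spec("beta")),
               "at least 4")
  expect_error(fit_growth(d[, setdiff(names(d), "length")], growth_spec()),
               "length")
})
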