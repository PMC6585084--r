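test_that("generation is deterministic and matches the published design", {
  cfg <- synth_config("F")
  d1 <- generate_growth(cfg, seed = 5)
  d2 <- generate_growth(cfg, seed = 5)
  expect_identical(d1, d2)
  expect_false(identical(d1$length, generate_growth(cfg, seed = 6)$length))

  expect_equal(length(unique(d1$fish_id)), 143)
  expect_equal(sort(unique(d1$age)), c(seq(14, 168, by = 14), 180))
  expect_true(all(is.na(d1$weight[d1$age %in% c(14, 28)])))
  expect_true(all(!is.na(d1$weight[!d1$age %in% c(14, 28)])))
  expect_true(all(table(d1$fish_id) == length(cfg$ages)))

  m <- generate_growth(synth_config("M"), seed = 5)
  expect_equal(length(unique(m$fish_id)), 116)
  expect_equal(max(m$age), 180)

  cfg0 <- cfg; cfg0$groups$n_growth <- rep(0L, 4)
  expect_error(generate_growth(cfg0, seed = 1), "empty design")
  cfg_bad <- cfg; cfg_bad$sigma <- -1
  expect_error(generate_growth(cfg_bad, seed = 1), "SDs")
})

test_that("configurations round-trip through YAML", {
  cfg <- synth_config("M")
  cfg$sd_beta <- 0.05
  cfg$groups$n_growth <- c(5L, 6L, 7L, 8L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synth_config(cfg, path)
  back <- read_synth_config(path)
  expect_equal(back$groups, cfg$groups)
  expect_equal(back$sd_beta, 0.05)
  expect_equal(back$behavior$freeze_s$count, cfg$behavior$freeze_s$count)
  # identical data from the restored configuration
  expect_identical(generate_growth(back, seed = 2),
                   generate_growth(cfg, seed = 2))
})

test_that("zero noise and zero random effects reproduce the model curve exactly", {
  cfg <- synth_config("F")
  cfg$groups$n_growth <- rep(2, 4)
  cfg$sd_beta <- 0; cfg$sigma <- 1e-300; cfg$weight_sd <- 0
  d <- generate_growth(cfg, seed = 8)
  g <- cfg$groups
  for (i in seq_len(nrow(g))) {
    rows <- d$line == g$line[i] & d$food == g$food[i]
    gp <- growth_params(g$a_mat[i], g$r[i], g$beta[i], cfg$c, cfg$L0)
    expect_equal(d$length[rows],
                 rep(biphasic_length(cfg$ages, gp, allometry_params()), 2),
                 tolerance = 1e-12)
  }
})

test_that("simulated residual autocorrelation matches the MA(2) covariance", {
  cfg <- synth_config("F")
  cfg$groups$n_growth <- c(10000, 0, 0, 0)
  cfg$sd_beta <- 0
  d <- generate_growth(cfg, seed = 9)
  gp <- growth_params(48, 0.018, 0.66, cfg$c, cfg$L0)
  mu <- biphasic_length(cfg$ages, gp, allometry_params())
  res <- matrix(d$length, ncol = length(cfg$ages), byrow = TRUE) -
    matrix(mu, nrow = 10000, ncol = length(cfg$ages), byrow = TRUE)
  V <- ma2_covariance(cfg$sigma, cfg$theta[1], cfg$theta[2], length(cfg$ages))
  r1_pred <- V[1, 2] / V[1, 1]
  r1_emp <- cor(as.vector(res[, -ncol(res)]), as.vector(res[, -1]))
  expect_lt(abs(r1_emp - r1_pred), 0.02)
  r3_emp <- cor(as.vector(res[, 1:(ncol(res) - 3)]), as.vector(res[, -(1:3)]))
  expect_lt(abs(r3_emp), 0.02) # no correlation beyond lag 2
})

test_that("behaviour generation matches the assay design and calibrated zeros", {
  cfg <- synth_config("F")
  b <- generate_behavior(cfg, seed = 10)
  expect_identical(b, generate_behavior(cfg, seed = 10))
  expect_equal(length(unique(b$fish_id)), 80)
  expect_equal(nrow(b), 480)
  expect_true(all(table(b$fish_id) == 6))
  expect_setequal(unique(b$condition), c("control", "novel", "threat"))
  expect_true(all(b$freeze_s <= 300))
  expect_true(all(b$bites >= 0))

  # degenerate all-structural-zero configuration
  cfg1 <- cfg
  cfg1$behavior$bites$zero[] <- c(30, 0, 0, 0) # pi -> 1
  b1 <- generate_behavior(cfg1, seed = 11)
  expect_true(all(b1$bites == 0))

  # zero fraction near the calibrated 33% target at large n
  cfg2 <- synth_config("F")
  cfg2$groups$n_behavior <- cfg2$groups$n_behavior * 30
  b2 <- generate_behavior(cfg2, seed = 12)
  expect_lt(abs(mean(b2$bites == 0) - 0.33), 0.05)
})
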