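# Shared fixtures: published parameter sets and small synthetic tables.

# Table-1 female generating parameter sets
gp_female_high <- function() growth_params(a_mat = 48, r = 0.018, beta = 0.66)
gp_female_low_large <- function() growth_params(a_mat = 97, r = 0.007, beta = 0.53)
gp_female_low_small <- function() growth_params(a_mat = 81, r = 0.007, beta = 0.53)

ap_default <- function() allometry_params(alpha = 2.7, b = 0.04)

# random valid parameter sets for property loops
random_growth_params <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    a_mat = runif(n, 20, 150),
    r = runif(n, 0, 0.05),
    beta = runif(n, 0.35, 0.85),
    c = runif(n, 0.05, 0.5),
    L0 = runif(n, 2, 6),
    alpha = runif(n, 2, 3.5),
    b = runif(n, 0.01, 0.1)
  )
}

# tiny noiseless trajectory table for fitting tests
tiny_trajectory <- function(n_per_group = 4, ages = seq(14, 180, by = 28),
                            sigma = 0, seed = 7) {
  set.seed(seed)
  cfg <- synth_config("F")
  cfg$groups$n_growth <- rep(n_per_group, 4)
  cfg$ages <- ages
  cfg$sigma <- sigma
  cfg$sd_beta <- 0
  generate_growth(cfg, seed = seed)
}

spec_label_of <- function(fit) biphasr:::spec_label(fit$spec)
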