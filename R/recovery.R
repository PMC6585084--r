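#' Parameter-recovery simulation studies
#'
#' Repeatedly simulates the published design at the published generating
#' values and refits the corresponding model, collecting per-replicate
#' estimates. These are the package's core validation experiments: if the
#' estimation machinery is sound, the median recovered parameters across
#' seeded replicates should sit within sampling error of the generating
#' values.
#'
#' @param sex `"F"` or `"M"`.
#' @param seeds Integer vector of replicate seeds.
#' @param config Generating [synth_config()]; defaults to the published
#'   design for `sex`.
#' @return `recover_growth()`: list with `group_params` (per-replicate,
#'   per-group a_mat/r/beta estimates and SEs, with a `seed` column),
#'   `coefs` (stacked coefficient tables) and `n_failed`.
#' @export
recover_growth <- function(sex, seeds = 1:20, config = synth_config(sex)) {
  gp_rows <- list(); cf_rows <- list(); failed <- 0L
  for (s in seeds) {
    d <- generate_growth(config, s)
    fit <- tryCatch(
      fit_growth(d, default_growth_spec(sex), default_growth_random_spec(sex)),
      error = function(e) NULL)
    if (is.null(fit)) { failed <- failed + 1L; next }
    gp <- fit$group_params; gp$seed <- s
    cf <- fit$coef_table; cf$seed <- s
    gp_rows[[length(gp_rows) + 1]] <- gp
    cf_rows[[length(cf_rows) + 1]] <- cf
  }
  if (!length(gp_rows)) stop("all ", length(seeds), " replicate fits failed")
  list(group_params = do.call(rbind, gp_rows),
       coefs = do.call(rbind, cf_rows),
       n_failed = failed)
}

#' @rdname recover_growth
#' @param response `"bites"` or `"freeze_s"`.
#' @param count_spec,zero_spec Fixed-effect structures fitted to each
#'   simulated dataset (defaults: the published final structures).
#' @return `recover_behavior()`: list with `count_coefs`, `zero_coefs`
#'   (stacked per-replicate tables with a `seed` column) and `n_failed`.
#' @export
recover_behavior <- function(sex, response = "bites", seeds = 1:20,
                             count_spec = ~food, zero_spec = ~ line + food,
                             config = synth_config(sex)) {
  cnt <- list(); zr <- list(); failed <- 0L
  for (s in seeds) {
    b <- generate_behavior(config, s)
    fit <- tryCatch(
      suppressWarnings(
        fit_zinb(b, response, count_spec = count_spec, zero_spec = zero_spec)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged ||
        !all(is.finite(c(fit$count_coefs$se, fit$zero_coefs$se)))) {
      failed <- failed + 1L; next
    }
    cc <- fit$count_coefs; cc$seed <- s
    zc <- fit$zero_coefs; zc$seed <- s
    cnt[[length(cnt) + 1]] <- cc
    zr[[length(zr) + 1]] <- zc
  }
  if (!length(cnt)) stop("all ", length(seeds), " replicate fits failed")
  list(count_coefs = do.call(rbind, cnt),
       zero_coefs = do.call(rbind, zr),
       n_failed = failed)
}

# median estimate for one group/parameter across replicates
median_group_value <- function(group_params, line, food, param) {
  v <- group_params[group_params$line == line & group_params$food == food,
                    param]
  stats::median(v)
}
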