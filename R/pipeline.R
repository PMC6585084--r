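#' Pipeline drivers
#'
#' Thin orchestration over the package: simulate a study, fit the growth
#' model, fit the behaviour models, writing CSV tables and JSON sidecars
#' under an output directory. These are the functions the numbered scripts
#' under `analysis/` call. CSVs are comma-separated UTF-8 with a header row
#' and empty fields for missing values.
#'
#' @name pipeline
NULL

log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

write_table <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, na = "")
  log_msg("wrote ", path)
  path
}

read_input <- function(input, required) {
  d <- if (is.character(input)) {
    if (!file.exists(input)) stop("input file not found: ", input)
    utils::read.csv(input, stringsAsFactors = FALSE)
  } else as.data.frame(input)
  miss <- setdiff(required, names(d))
  if (length(miss)) stop("input lacks required column(s): ",
                         paste(miss, collapse = ", "))
  d
}

#' Simulate a synthetic study to disk
#'
#' Writes the growth-trajectory and behaviour CSVs plus a JSON file with
#' the generating truth (group parameter values and noise settings).
#'
#' @param out_dir Output directory (created if needed).
#' @param sex `"F"` or `"M"`.
#' @param seed Integer seed; identical seed and config give identical files.
#' @param config A [synth_config()]; defaults to the published design.
#' @return Invisibly, named character vector of the three file paths.
#' @export
run_simulate <- function(out_dir, sex = c("F", "M"), seed = 1,
                         config = synth_config(sex)) {
  sex <- match.arg(sex)
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  growth <- generate_growth(config, seed)
  behavior <- generate_behavior(config, seed)
  paths <- c(
    growth = write_table(growth, file.path(out_dir, paste0("growth_", sex, ".csv"))),
    behavior = write_table(behavior, file.path(out_dir, paste0("behavior_", sex, ".csv"))),
    truth = file.path(out_dir, paste0("truth_", sex, ".json")))
  truth <- list(sex = sex, seed = seed,
                groups = config$groups,
                ages = config$ages,
                noise = list(sd_beta = config$sd_beta, sd_r = config$sd_r,
                             sigma = config$sigma, theta = config$theta,
                             weight_sd = config$weight_sd),
                constants = list(c = config$c, L0 = config$L0,
                                 alpha = config$alpha, b = config$b),
                behavior = config$behavior)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  log_msg("wrote ", paths["truth"])
  invisible(paths)
}

#' Run the growth analysis on a trajectory table
#'
#' Estimates the weight-length allometry from the data when weights are
#' available (otherwise uses the supplied defaults), fits the biphasic NLME
#' (optionally choosing the fixed-effect structure by AIC over candidate
#' specs), optionally simplifies by backward elimination, and writes the
#' coefficient table, a per-group parameter table (one row per line x food
#' combination with a_mat, r, beta and SEs) and a JSON sidecar.
#'
#' @param input Trajectory CSV path or data frame.
#' @param out_dir Output directory.
#' @param sex `"F"` or `"M"` (sets the default fixed/random structure).
#' @param auto_select Choose the fixed-effect structure by AIC over
#'   `candidates` instead of using the published structure.
#' @param candidates Candidate [growth_spec()] list for `auto_select`
#'   (default the full 125-model lattice).
#' @param backward Apply [backward_eliminate()] after fitting (the
#'   published workflow does this for males).
#' @param c_value,l0 Model constants.
#' @return Invisibly, the final `growth_fit`.
#' @export
run_fit_growth <- function(input, out_dir, sex = c("F", "M"),
                           auto_select = FALSE, candidates = NULL,
                           backward = (sex == "M"), c_value = 0.15, l0 = 4.0) {
  sex <- match.arg(sex)
  d <- read_input(input, c("fish_id", "line", "food", "age", "length"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ap <- allometry_params()
  if ("weight" %in% names(d) &&
      sum(stats::complete.cases(d$length, d$weight)) >= 10) {
    ap <- fit_allometry(d)
    log_msg(sprintf("allometry from data: alpha = %.3f, b = %.4f",
                    ap$alpha, ap$b))
  }
  random_spec <- default_growth_random_spec(sex)
  if (auto_select) {
    if (is.null(candidates)) candidates <- growth_spec_lattice()
    log_msg("AIC selection over ", length(candidates), " candidate structures")
    sel <- aic_select(d, candidates, random_spec, c = c_value, L0 = l0, ap = ap)
    fit <- sel$best
    write_table(sel$table, file.path(out_dir, paste0("aic_growth_", sex, ".csv")))
  } else {
    fit <- fit_growth(d, default_growth_spec(sex), random_spec,
                      c = c_value, L0 = l0, ap = ap)
  }
  if (backward) fit <- backward_eliminate(fit)
  write_table(fit$coef_table,
              file.path(out_dir, paste0("growth_coefficients_", sex, ".csv")))
  write_table(fit$group_params,
              file.path(out_dir, paste0("growth_group_params_", sex, ".csv")))
  sidecar <- list(sex = sex, structure = spec_label(fit$spec),
                  random = unclass(fit$random_spec),
                  logLik = fit$logLik, AIC = fit$AIC,
                  sigma = fit$sigma, theta = as.list(fit$theta),
                  re_sd = as.list(fit$re_sd),
                  allometry = list(alpha = ap$alpha, b = ap$b),
                  constants = list(c = c_value, L0 = l0),
                  n_fish = fit$n_fish, n_obs = fit$n_obs,
                  converged = fit$converged)
  jsonlite::write_json(sidecar, file.path(out_dir, paste0("growth_fit_", sex, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Run the behaviour analysis on an assay table
#'
#' Fits the zero-inflated NB mixed model for both responses (bites,
#' freezing seconds), optionally selecting the fixed-effect structure of
#' each part by AIC, and writes per-response coefficient tables plus a
#' summary of which predictors affect each response and part.
#'
#' @param input Behaviour CSV path or data frame.
#' @param out_dir Output directory.
#' @param auto_select Select count/zero structures by AIC over `candidates`.
#' @param candidates Candidate list for [aic_select_zinb()] (default the
#'   25-model lattice).
#' @return Invisibly, named list of `zinb_fit` objects.
#' @export
run_fit_behavior <- function(input, out_dir, auto_select = FALSE,
                             candidates = NULL) {
  d <- read_input(input, c("fish_id", "line", "food", "condition",
                           "replicate", "bites", "freeze_s"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fits <- list()
  summary_rows <- list()
  for (resp in c("bites", "freeze_s")) {
    if (auto_select) {
      if (is.null(candidates)) candidates <- zinb_spec_lattice()
      sel <- aic_select_zinb(d, resp, candidates)
      fit <- sel$best
      write_table(sel$table, file.path(out_dir, paste0("aic_", resp, ".csv")))
    } else {
      fit <- fit_zinb(d, resp)
    }
    fits[[resp]] <- fit
    write_table(fit$count_coefs,
                file.path(out_dir, paste0(resp, "_count_coefficients.csv")))
    write_table(fit$zero_coefs,
                file.path(out_dir, paste0(resp, "_zero_coefficients.csv")))
    terms_of <- function(f) {
      tl <- attr(stats::terms(f), "term.labels")
      if (length(tl)) paste(tl, collapse = " + ") else "1"
    }
    summary_rows[[resp]] <- data.frame(
      response = resp,
      part = c("count", "zero"),
      predictors = c(terms_of(fit$count_spec), terms_of(fit$zero_spec)),
      AIC = fit$AIC, stringsAsFactors = FALSE)
    sidecar <- list(response = resp, logLik = fit$logLik, AIC = fit$AIC,
                    k = fit$k, re_sd = as.list(fit$re_sd),
                    repeatability = repeatability_icc(fit),
                    converged = fit$converged, n_fish = fit$n_fish,
                    n_obs = fit$n_obs)
    jsonlite::write_json(sidecar, file.path(out_dir, paste0(resp, "_fit.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  write_table(do.call(rbind, summary_rows),
              file.path(out_dir, "behavior_summary.csv"))
  invisible(fits)
}
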