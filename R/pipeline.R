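#' Configuration for a full pipeline run
#'
#' @param cohort A [cohort_config()] (synthetic input mode), or a
#'   pre-generated `"synthetic_cohort"`.
#' @param fit A [fit_settings()].
#' @param bands Band definitions.
#' @param alpha Family-wise level for all Holm corrections.
#' @param out_dir Output directory, or `NULL` for no files.
#' @param seed Optional seed overriding the cohort config's seed.
#' @param write_spectra Also write the (large) long-format spectra CSV.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(cohort = cohort_config(), fit = fit_settings(),
                       bands = band_definitions(), alpha = 0.05,
                       out_dir = NULL, seed = NULL, write_spectra = FALSE) {
  if (!is.null(seed) && inherits(cohort, "cohort_config")) {
    cohort$seed <- as.integer(seed)
  }
  structure(list(cohort = cohort, fit = fit, bands = bands, alpha = alpha,
                 out_dir = out_dir, seed = seed,
                 write_spectra = write_spectra),
            class = "run_config")
}

#' Run the full analysis pipeline on one cohort
#'
#' Generate (or accept) a cohort, estimate and fit every spectrum, apply the
#' paired quality filter, derive per-patient features, run the eight-test
#' EEG battery with Holm correction, fit the three band-power regressions,
#' and compute the clinical pre/post comparison and remission rate. With an
#' output directory set, writes `features.csv`, `fits.csv`,
#' `eeg_tests.csv`, `band_regressions.csv`, `report.json` (and optionally
#' `spectra.csv`). Reruns with the same config are deterministic.
#'
#' @param config A [run_config()].
#' @return A list of class `"run_report"`: `features`, `eeg_tests`,
#'   `band_regressions`, `clinical`, `config_used`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (inherits(config$cohort, "synthetic_cohort")) {
    config$cohort
  } else {
    make_cohort(config$cohort)
  }
  fits <- fit_cohort(cohort, config$fit)
  features <- cohort_features(cohort, fits, bands = config$bands,
                              r2_min = config$fit$r2_min)
  battery <- eeg_feature_tests(features, alpha = config$alpha)
  regs <- lapply(config$bands$name, function(b) {
    tryCatch(band_power_regression(features, b, alpha = config$alpha),
             error = function(e) {
               message("band regression skipped for ", b, ": ",
                       conditionMessage(e))
               NULL
             })
  })
  names(regs) <- config$bands$name
  hamd <- paired_test(features$hamd_pre, features$hamd_post,
                      choice = "wilcoxon")
  clinical <- list(
    hamd_test = hamd,
    remission_rate = remission_rate(features$hamd_pre, features$hamd_post),
    n = nrow(features))
  report <- structure(list(features = features,
                           eeg_tests = battery$tests,
                           eeg_results = battery$results,
                           band_regressions = regs,
                           clinical = clinical,
                           config_used = cohort$config),
                      class = "run_report")
  if (!is.null(config$out_dir)) {
    write_run_report(report, fits, cohort, config)
  }
  report
}

reg_summary <- function(reg) {
  if (is.null(reg)) return(NULL)
  list(band = reg$band, n = reg$n, adj_r_squared = reg$adj_r_squared,
       f_statistic = reg$f_statistic, f_df1 = reg$f_df1, f_df2 = reg$f_df2,
       f_p = reg$f_p, terms = reg$terms, holm = reg$holm)
}

write_run_report <- function(report, fits, cohort, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  utils::write.csv(report$features, p("features.csv"), row.names = FALSE)
  utils::write.csv(fits_table(fits), p("fits.csv"), row.names = FALSE)
  utils::write.csv(report$eeg_tests, p("eeg_tests.csv"), row.names = FALSE)
  regs <- Filter(Negate(is.null), report$band_regressions)
  if (length(regs)) {
    reg_tab <- do.call(rbind, lapply(regs, function(r) {
      cbind(band = r$band, r$terms,
            adj_r_squared = r$adj_r_squared, f_p = r$f_p,
            alpha_adj = r$holm$alpha_adj[match(r$terms$term, r$holm$label)])
    }))
    utils::write.csv(reg_tab, p("band_regressions.csv"), row.names = FALSE)
  }
  if (isTRUE(config$write_spectra)) {
    utils::write.csv(spectra_table(cohort), p("spectra.csv"),
                     row.names = FALSE)
  }
  json <- list(
    seed = cohort$config$seed,
    config = unclass(cohort$config),
    eeg_tests = report$eeg_tests,
    band_regressions = lapply(report$band_regressions, reg_summary),
    clinical = list(
      test = report$clinical$hamd_test$test_name,
      statistic = report$clinical$hamd_test$statistic,
      p = report$clinical$hamd_test$p,
      effect = report$clinical$hamd_test$effect,
      remission_rate = report$clinical$remission_rate,
      n = report$clinical$n))
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s cohort, %d patients retained\n",
              x$config_used$treatment, nrow(x$features)))
  print(x$eeg_tests[, c("feature", "test", "n", "statistic", "p",
                        "effect", "alpha_adj", "reject_stepdown")],
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Combined clinical-outcome table across treatment cohorts
#'
#' Binds per-cohort feature tables, normalizes the HAM-D scores of each
#' scale version onto the common 0-1 range, and exposes the candidate
#' columns used by [exhaustive_outcome_search()].
#'
#' @param ... Feature tables from [cohort_features()] or
#'   [ground_truth_features()] (must carry `hamd_pre`, `hamd_post`,
#'   `hamd_version`, `treatment`, `n_treatments` and the feature columns).
#' @return Data frame with `hamd_pre_norm` and `hamd_post_norm` added.
#' @export
clinical_outcome_table <- function(...) {
  tabs <- list(...)
  cols <- Reduce(intersect, lapply(tabs, names))
  df <- do.call(rbind, lapply(tabs, function(t) t[, cols]))
  df$hamd_pre_norm <- mapply(normalize_hamd, df$hamd_pre, df$hamd_version)
  df$hamd_post_norm <- mapply(normalize_hamd, df$hamd_post, df$hamd_version)
  df
}
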