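#' Study configuration for the end-to-end sway analysis
#'
#' Bundles the cohort simulation settings, the models to compare, the
#' cross-validation layout and the COP-path window policy into one object
#' that round-trips losslessly through YAML ([write_study_config()] /
#' [read_study_config()]).
#'
#' @param sim a [sim_config()].
#' @param algorithms character vector of model names (see [model_spec()]).
#' @param k folds for cross-validation.
#' @param seed master seed; propagates to the simulator, fold partition and
#'   stochastic learners.
#' @param windowing COP-path target policy, `"window"` or `"full"` (see
#'   [feature_table()]).
#' @return A list of class `study_config`.
#' @export
study_config <- function(sim = sim_config(seed = seed),
                         algorithms = c("lsboost", "bagging", "svm",
                                        "ann", "gp"),
                         k = 5, seed = 1L,
                         windowing = c("window", "full")) {
  windowing <- match.arg(windowing)
  structure(list(sim = sim, algorithms = algorithms, k = k,
                 seed = as.integer(seed), windowing = windowing),
            class = "study_config")
}

#' @rdname study_config
#' @param config a `study_config`.
#' @param path YAML file path.
#' @export
write_study_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$base_intensity <- as.list(x$sim$base_intensity)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- do.call(sim_config, c(x$sim[setdiff(names(x$sim), "base_intensity")],
                               list(base_intensity =
                                      unlist(x$sim$base_intensity))))
  study_config(sim = sim, algorithms = x$algorithms, k = x$k,
               seed = x$seed, windowing = x$windowing)
}

#' Run the full simulate -> metrics -> predict -> agree study
#'
#' Orchestrates the whole analysis: simulate a paired cohort, extract the
#' four sway metrics and the COP-path target, assess concurrent validity of
#' each metric (Spearman), train the requested models under shared k-fold
#' cross-validation, and report per-fold and best-fold agreement. Fully
#' deterministic given `config$seed`.
#'
#' If `output_dir` is given, writes `validity.csv`, `folds.csv`,
#' `features.csv`, `best_folds.json` and `summary.json` there.
#'
#' @param config a [study_config()].
#' @param output_dir optional directory for the report files.
#' @return A list of class `study_report`: `validity` (per-metric rho/p),
#'   `comparison` ([run_model_comparison()] result), `best_reports` (per
#'   model, the [agreement_report()] of its best fold), `features` (the
#'   [feature_table()]) and `config`.
#' @export
run_study <- function(config = study_config(), output_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  cohort <- simulate_cohort(config$sim)
  features <- feature_table(cohort, windowing = config$windowing)
  validity <- validity_table(features)
  specs <- lapply(config$algorithms, function(a) {
    model_spec(a, seed = config$seed)
  })
  names(specs) <- config$algorithms
  comparison <- run_model_comparison(features, specs, k = config$k,
                                     seed = config$seed)
  best_reports <- lapply(names(comparison$folds), function(m) {
    comparison$folds[[m]][[comparison$best_fold[[m]]]]$agreement
  })
  names(best_reports) <- names(comparison$folds)
  report <- structure(list(validity = validity, comparison = comparison,
                           best_reports = best_reports, features = features,
                           config = config),
                      class = "study_report")
  if (!is.null(output_dir)) write_study_report(report, output_dir)
  report
}

report_summary_list <- function(report) {
  comp <- report$comparison
  mean_icc <- tapply(comp$summary$icc, comp$summary$model, mean)
  list(
    n_trials = nrow(report$features),
    k = comp$k,
    seed = report$config$seed,
    windowing = report$config$windowing,
    validity = report$validity,
    folds = comp$summary,
    mean_icc = as.list(mean_icc),
    best_fold = as.list(comp$best_fold),
    best_reports = lapply(report$best_reports, function(a) {
      list(rho = a$rho, p_value = a$p_value, icc = a$icc,
           icc_ci95 = a$icc_ci95, bias = a$bias, loa = a$loa,
           cv_pct = a$cv_pct, slope = a$slope, offset = a$offset, n = a$n)
    })
  )
}

write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$validity, file.path(dir, "validity.csv"),
            row.names = FALSE)
  write.csv(report$comparison$summary, file.path(dir, "folds.csv"),
            row.names = FALSE)
  write.csv(report$features, file.path(dir, "features.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    lapply(report$best_reports, function(a) {
      list(rho = a$rho, icc = a$icc, icc_ci95 = a$icc_ci95, bias = a$bias,
           loa = a$loa, cv_pct = a$cv_pct, slope = a$slope,
           offset = a$offset)
    }),
    file.path(dir, "best_folds.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report_summary_list(report),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n\nConcurrent validity (Spearman vs COP path):\n")
  print(x$validity, row.names = FALSE)
  cat("\n")
  print(x$comparison)
  invisible(x)
}
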