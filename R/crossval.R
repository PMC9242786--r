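#' Specify one of the five COP-path regression models
#'
#' Supported algorithms and their default hyperparameters:
#'
#' * `"lsboost"`: least-squares gradient boosting, 100 regression trees of
#'   depth 3, learning rate 0.1 (via \pkg{xgboost}).
#' * `"bagging"`: bootstrap aggregation of 100 regression trees grown on all
#'   features (via \pkg{randomForest} with `mtry = p`).
#' * `"svm"`: epsilon-insensitive support vector regression with RBF kernel;
#'   epsilon is set per training fold to one tenth of the IQR-based robust
#'   sd of the targets, cost defaults to 1 (via \pkg{e1071}).
#' * `"ann"`: feedforward network with two hidden layers of 3 and 4 tanh
#'   nodes, linear output, full-batch BFGS training, max 1000 iterations.
#' * `"gp"`: Gaussian process regression with squared-exponential kernel,
#'   constant mean basis, amplitude initialized to `sd(y)/2`, length-scale
#'   and noise optimized by marginal likelihood.
#'
#' @param algorithm one of `"lsboost"`, `"bagging"`, `"svm"`, `"ann"`,
#'   `"gp"`.
#' @param hyper named list overriding default hyperparameters.
#' @param seed integer seed for stochastic learners (weight initialization,
#'   bootstrap resampling); mandatory.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("lsboost", "bagging", "svm", "ann", "gp"),
                       hyper = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  h <- default_hyper(algorithm)
  h[names(hyper)] <- hyper
  structure(list(algorithm = algorithm, hyper = h, seed = as.integer(seed)),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
default_model_specs <- function(seed = 1L) {
  algos <- c("lsboost", "bagging", "svm", "ann", "gp")
  setNames(lapply(algos, function(a) model_spec(a, seed = seed)), algos)
}

#' Seeded k-fold partition
#'
#' Randomly partitions `n` rows into `k` folds whose sizes differ by at most
#' one. Deterministic given the seed; the caller's RNG state is untouched.
#'
#' @param n number of rows (or a [feature_table()], in which case its row
#'   count is used).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param groups optional grouping vector of length `n` (e.g. subject ids).
#'   When given, whole groups are assigned to folds, so no subject
#'   contributes trials to both a training and a test fold; trial counts per
#'   fold may then differ by more than one.
#' @return Integer vector of length `n` with fold labels `1..k`.
#' @export
make_folds <- function(n, k = 5, seed = 1L, groups = NULL) {
  if (inherits(n, "data.frame")) n <- nrow(n)
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  if (is.null(groups)) {
    if (k > n) stop("invalid config: more folds than rows", call. = FALSE)
    labels <- rep(seq_len(k), length.out = n)
    return(with_seed(seed, sample(labels)))
  }
  if (length(groups) != n) {
    stop("`groups` must have length `n`", call. = FALSE)
  }
  ug <- unique(groups)
  if (k > length(ug)) {
    stop("invalid config: more folds than groups", call. = FALSE)
  }
  glabels <- rep(seq_len(k), length.out = length(ug))
  glabels <- with_seed(seed, sample(glabels))
  unname(glabels[match(groups, ug)])
}

standardize_train_test <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  s <- apply(x_train, 2, sd)
  s[s == 0] <- 1
  list(train = sweep(sweep(x_train, 2, mu), 2, s, "/"),
       test = sweep(sweep(x_test, 2, mu), 2, s, "/"))
}

FEATURES <- c("rms", "range", "ac", "sd")

#' Fit a model on the training folds and predict the held-out fold
#'
#' Features are z-scored using training-fold statistics only, and
#' data-derived hyperparameters (SVM epsilon, GP amplitude initialization)
#' are computed from training-fold targets only, so no information leaks
#' from the held-out fold into training.
#'
#' @param table a [feature_table()].
#' @param spec a [model_spec()].
#' @param fold_labels integer fold labels from [make_folds()].
#' @param fold_index which fold to hold out.
#' @return A list of class `fold_result` with `fold_index`, `test_keys`,
#'   `predictions`, `actuals`, `agreement` ([agreement_report()]) and
#'   `converged`.
#' @export
fit_predict_fold <- function(table, spec, fold_labels, fold_index) {
  stopifnot(inherits(spec, "model_spec"))
  test <- fold_labels == fold_index
  if (sum(!test) < 10L) stop("need at least 10 training rows", call. = FALSE)
  x <- as.matrix(table[, FEATURES])
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  y <- table$cop_path_mm
  xs <- standardize_train_test(x[!test, , drop = FALSE],
                               x[test, , drop = FALSE])
  fit <- learner_registry[[spec$algorithm]](xs$train, y[!test], spec$hyper,
                                            seed = spec$seed + fold_index)
  preds <- fit$predict_fn(xs$test)
  structure(list(fold_index = fold_index,
                 test_keys = table[test, c("subject_id", "condition")],
                 predictions = preds, actuals = y[test],
                 agreement = agreement_report(y[test], preds),
                 converged = fit$converged),
            class = "fold_result")
}

#' Compare the five models under a shared k-fold partition
#'
#' Runs every model over the same seeded fold partition (a paired design:
#' per-fold results are directly comparable across models) and identifies,
#' per model, the fold with the highest ICC(2,1) between held-out
#' predictions and actual COP path lengths.
#'
#' @param table a [feature_table()].
#' @param specs list of [model_spec()] (default all five).
#' @param k number of folds (default 5).
#' @param seed seed for the fold partition.
#' @return A list of class `model_comparison` with elements `folds` (per
#'   model, a list of `fold_result`), `summary` (data frame
#'   `model, fold, icc, icc_lo, icc_hi, rho, bias, loa_lo, loa_hi, cv_pct,
#'   slope, offset`), `best_fold` (named integer vector, argmax-ICC fold per
#'   model) and `fold_labels`.
#' @export
run_model_comparison <- function(table, specs = default_model_specs(seed),
                                 k = 5, seed = 1L) {
  fold_labels <- make_folds(nrow(table), k = k, seed = seed)
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, `[[`, "", "algorithm")
  }
  folds <- lapply(specs, function(spec) {
    lapply(seq_len(k), function(i) {
      fit_predict_fold(table, spec, fold_labels, i)
    })
  })
  summary <- do.call(rbind, lapply(names(folds), function(m) {
    do.call(rbind, lapply(folds[[m]], function(fr) {
      a <- fr$agreement
      data.frame(model = m, fold = fr$fold_index, icc = a$icc,
                 icc_lo = a$icc_ci95[1], icc_hi = a$icc_ci95[2],
                 rho = a$rho, bias = a$bias, loa_lo = a$loa[1],
                 loa_hi = a$loa[2], cv_pct = a$cv_pct, slope = a$slope,
                 offset = a$offset, stringsAsFactors = FALSE)
    }))
  }))
  rownames(summary) <- NULL
  best <- vapply(folds, function(frs) {
    which.max(vapply(frs, function(fr) fr$agreement$icc, 0))
  }, 0L)
  structure(list(folds = folds, summary = summary, best_fold = best,
                 fold_labels = fold_labels, k = k, seed = seed),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  mean_icc <- tapply(x$summary$icc, x$summary$model, mean)
  cat(sprintf("<model_comparison> %d models x %d folds\n",
              length(x$folds), x$k))
  for (m in names(x$folds)) {
    cat(sprintf("  %-8s mean ICC %.3f  best fold %d (ICC %.3f)\n",
                m, mean_icc[[m]], x$best_fold[[m]],
                max(x$summary$icc[x$summary$model == m])))
  }
  invisible(x)
}
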