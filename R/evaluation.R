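# Leave-one-patient-out (LOPO) evaluation harness.
#
# Each patient in turn is held out; the classifier is trained on the labeled
# sessions of all remaining patients and predicts every session of the test
# patient independently. Predictions are scored against the patient's
# eventual decision class at every offset (including pre-decision,
# "unlabeled" sessions), pooled by decision-aligned offset into a BER series,
# and summarised by wBER.

#' Leave-one-patient-out folds
#'
#' @param cohort a `gbm_cohort` with at least two patients.
#' @return A list with one element per patient: `list(test_patient_id,
#'   train, test)` where `train` is the cohort without that patient's
#'   sessions and `test` is the patient's data frame rows.
#' @export
lopo_folds <- function(cohort) {
  stopifnot(inherits(cohort, "gbm_cohort"))
  pids <- unique(cohort$data$patient_id)
  if (length(pids) < 2L)
    gbm_abort("leave-one-patient-out needs at least 2 patients",
              "gbm_fold_error")
  lapply(pids, function(pid) {
    train <- cohort
    train$data <- cohort$data[cohort$data$patient_id != pid, , drop = FALSE]
    list(test_patient_id = pid,
         train = train,
         test = cohort$data[cohort$data$patient_id == pid, , drop = FALSE])
  })
}

# deterministic sub-seed for (run seed, fold, classifier); kept below 2^31
derive_seed <- function(seed, fold, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.numeric(seed) * 48271 + fold * 9973 + h) %% 2147483647 + 1
}

#' Train on one fold and predict the held-out patient
#'
#' Trains the classifier on the labeled sessions of the training cohort
#' (restricted to the selected feature columns) and predicts each session of
#' the test patient independently. The truth for every test session is the
#' patient's decision class. Matrices must be fully observed: in the
#' complete-data variant the caller filters to complete rows, in the imputed
#' variant it imputes first.
#'
#' @param spec a [classifier_spec()].
#' @param train a labeled `gbm_cohort` (training patients).
#' @param test data frame of the held-out patient's sessions.
#' @param features character vector of feature columns to use.
#' @return A `fold_result` data frame with columns `patient_id`, `offset`,
#'   `truth`, `predicted`; zero rows when the patient has no eligible
#'   session.
#' @export
train_and_predict <- function(spec, train, test, features = train$schema$names) {
  train <- require_labels(train)
  d <- train$data
  lab <- d[d$label != "unlabeled", , drop = FALSE]
  X_train <- as.matrix(lab[, features, drop = FALSE])
  if (anyNA(X_train))
    gbm_abort("training features contain missing values; filter to complete rows or impute first",
              "gbm_missing_error")
  X_test <- as.matrix(test[, features, drop = FALSE])
  if (anyNA(X_test))
    gbm_abort("test features contain missing values; filter to complete rows or impute first",
              "gbm_missing_error")
  pred <- if (nrow(X_test)) {
    classifier_predict(spec, X_train, lab$label, X_test)
  } else character(0)
  out <- data.frame(patient_id = test$patient_id,
                    offset = test$offset,
                    truth = test$decision_class,
                    predicted = pred,
                    stringsAsFactors = FALSE)
  class(out) <- c("fold_result", "data.frame")
  out
}

#' Leave-one-patient-out evaluation of one classifier
#'
#' Runs the full LOPO protocol: for every fold, the classifier is trained on
#' the labeled sessions of the remaining patients and predicts the held-out
#' patient's sessions; per-fold predictions are pooled by decision-aligned
#' offset into a balanced-error-rate series and summarised by the weighted
#' BER. In the `"complete"` variant only sessions fully observed on the
#' selected features take part (both for training and testing); in the
#' `"imputed"` variant a volume-conditioned imputation model is fitted per
#' fold on the training patients' labeled sessions only (no test-patient
#' leakage) and applied to training and test sessions alike.
#'
#' @param cohort a `gbm_cohort` (labels are propagated if absent).
#' @param spec a [classifier_spec()].
#' @param features `"all"`, `"perfusion"`, `"diffusion"` or
#'   `"spectroscopy"`; single-modality subsets keep the two clinical
#'   features and drop volumes from the classifier's view (volumes are still
#'   used by the imputation rules).
#' @param variant `"complete"` or `"imputed"`.
#' @param seed integer; all stochastic learners derive per-fold sub-seeds
#'   from it, so the report is reproducible.
#' @return An object of class `evaluation_report`: list with `classifier`,
#'   `variant`, `features`, `series` (a [ber_series()]), `wber`, `folds`
#'   (per-fold sizes and skipped sessions) and `substitution` metadata.
#' @export
evaluate <- function(cohort, spec,
                     features = c("all", "perfusion", "diffusion", "spectroscopy"),
                     variant = c("complete", "imputed"),
                     seed = 1L) {
  stopifnot(inherits(cohort, "gbm_cohort"), inherits(spec, "classifier_spec"))
  features <- match.arg(features)
  variant <- match.arg(variant)
  cohort <- require_labels(cohort)
  feat_cols <- modality_features(cohort$schema, features)
  if (features != "all")  # volumes stay out of single-modality classifiers
    feat_cols <- setdiff(feat_cols, .VOLUME_FEATURES)

  folds <- lopo_folds(cohort)
  results <- vector("list", length(folds))
  fold_log <- data.frame(patient_id = character(length(folds)),
                         n_train = integer(length(folds)),
                         n_test = integer(length(folds)),
                         n_skipped = integer(length(folds)))
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    train <- f$train
    test <- f$test
    if (variant == "imputed") {
      model <- fit_imputer(train)
      train <- impute_cohort(train, model)
      test_cohort <- cohort
      test_cohort$data <- test
      test <- impute_cohort(test_cohort, model)$data
    } else {
      ok_train <- stats::complete.cases(train$data[, feat_cols, drop = FALSE])
      train$data <- train$data[ok_train, , drop = FALSE]
      ok_test <- stats::complete.cases(test[, feat_cols, drop = FALSE])
      test <- test[ok_test, , drop = FALSE]
    }
    set.seed(derive_seed(seed, i, spec$label))
    results[[i]] <- train_and_predict(spec, train, test, feat_cols)
    fold_log$patient_id[i] <- f$test_patient_id
    fold_log$n_train[i] <- sum(train$data$label != "unlabeled")
    fold_log$n_test[i] <- nrow(test)
    fold_log$n_skipped[i] <- nrow(f$test) - nrow(test)
  }
  pooled <- do.call(rbind, results)
  if (nrow(pooled) == 0L)
    gbm_abort("no test session was eligible in any fold", "gbm_fold_error")
  offs <- sort(unique(pooled$offset), decreasing = TRUE)
  ber <- vapply(offs, function(o) {
    sel <- pooled$offset == o
    balanced_error_rate(pooled$truth[sel], pooled$predicted[sel])
  }, numeric(1))
  n <- vapply(offs, function(o) sum(pooled$offset == o), integer(1))
  series <- ber_series(offs, ber, n)
  structure(list(classifier = spec$label,
                 variant = variant,
                 features = features,
                 series = series,
                 wber = weighted_ber(series),
                 folds = fold_log,
                 substitution = spec$substitution,
                 seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s | %s features, %s data\n",
              x$classifier, x$features, x$variant))
  s <- x$series
  cat(sprintf("  %-6s %6s %4s\n", "offset", "BER", "n"))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-6s %6.3f %4d\n", format_offset_label(s$offset[i]),
                s$ber[i], s$n[i]))
  cat(sprintf("  wBER = %.3f\n", x$wber))
  if (!is.null(x$substitution)) cat("  note:", x$substitution, "\n")
  invisible(x)
}

#' Compare classifiers on complete and imputed data
#'
#' Evaluates each specification under both data variants and tabulates the
#' wBER values plus their per-classifier average; the `n_best` classifiers
#' by average are flagged.
#'
#' @param cohort a `gbm_cohort`.
#' @param specs list of [classifier_spec()] objects.
#' @param seed integer run seed.
#' @param features feature subset passed to [evaluate()].
#' @param n_best how many leading rows to flag.
#' @return A data frame with columns `classifier`, `complete`, `imputed`,
#'   `average`, `best`.
#' @export
compare_classifiers <- function(cohort, specs, seed = 1L, features = "all",
                                n_best = 6L) {
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  if (!length(specs))
    gbm_abort("compare_classifiers needs at least one classifier",
              "gbm_classifier_error")
  rows <- lapply(specs, function(spec) {
    comp <- evaluate(cohort, spec, features = features,
                     variant = "complete", seed = seed)
    imp <- evaluate(cohort, spec, features = features,
                    variant = "imputed", seed = seed)
    data.frame(classifier = spec$label, complete = comp$wber,
               imputed = imp$wber, average = (comp$wber + imp$wber) / 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$best <- rank(out$average, ties.method = "min") <= min(n_best, nrow(out))
  out
}
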