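# Volume-conditioned imputation of missing modality features.
#
# Rationale: if the volume of the tumour region a feature is measured over is
# exactly zero, the missing measurement is taken to come from healthy tissue —
# perfusion ratios are normalised to normal-appearing white matter and are
# therefore filled with 1, while diffusion and spectroscopy features are
# filled with the mean over responsive-labeled sessions (the closest available
# surrogate for healthy tissue). Missing values not associated with a zero
# region volume are filled with the mean over all labeled sessions.

#' Fit the volume-conditioned imputation model
#'
#' Learns per-feature replacement values from the labeled sessions of a
#' cohort: the mean over responsive-labeled sessions where the feature is
#' observed (`responsive_mean`), and the mean over all labeled sessions where
#' it is observed (`labeled_mean`). The perfusion fill constant is exactly 1
#' (the normal-tissue value of a NAWM-normalised ratio). Features never
#' observed among the qualifying sessions are absent from the corresponding
#' map; [impute_point()] raises an error if such a feature is required.
#'
#' @param cohort a labeled `gbm_cohort` (labels are propagated if absent).
#'   Only rows with `label != "unlabeled"` contribute.
#' @param schema a [gbm_schema()]; defaults to the cohort's.
#' @return An object of class `imputation_model`: list with named numeric
#'   vectors `responsive_mean` and `labeled_mean` (covering non-always-present
#'   features observed at least once) and `perfusion_fill = 1`.
#' @export
fit_imputer <- function(cohort, schema = cohort$schema) {
  cohort <- require_labels(cohort)
  d <- cohort$data
  labeled <- d[d$label != "unlabeled", , drop = FALSE]
  if (nrow(labeled) == 0L)
    gbm_abort("fit_imputer needs at least one labeled session",
              "gbm_imputation_error")
  feats <- setdiff(schema$names, schema$always_present)
  col_mean <- function(rows, f) {
    v <- rows[[f]]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NULL
  }
  resp <- labeled[labeled$label == "responsive", , drop = FALSE]
  responsive_mean <- unlist(lapply(feats, function(f) {
    m <- col_mean(resp, f)
    if (is.null(m)) NULL else stats::setNames(m, f)
  }))
  labeled_mean <- unlist(lapply(feats, function(f) {
    m <- col_mean(labeled, f)
    if (is.null(m)) NULL else stats::setNames(m, f)
  }))
  empty <- stats::setNames(numeric(0), character(0))
  structure(
    list(responsive_mean = responsive_mean %||% empty,
         labeled_mean = labeled_mean %||% empty,
         perfusion_fill = 1),
    class = "imputation_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.imputation_model <- function(x, ...) {
  cat(sprintf("<imputation_model> %d labeled means, %d responsive means, perfusion fill = %g\n",
              length(x$labeled_mean), length(x$responsive_mean),
              x$perfusion_fill))
  invisible(x)
}

# Replacement value for one missing feature at one session. `row` is a 1-row
# slice giving the session's volumes.
.impute_value <- function(feature, row, model, schema) {
  region <- schema$region[[feature]]
  modality <- schema$modality[[feature]]
  zero_vol <- !is.na(region) &&
    row[[region_volume_feature(region)]] == 0   # exact zero: region absent
  if (zero_vol) {
    if (modality == "perfusion") return(model$perfusion_fill)
    fill <- model$responsive_mean[feature]
    if (is.na(fill))
      gbm_abort(paste0("unfittable feature '", feature,
                       "': never observed among responsive-labeled sessions"),
                "gbm_unfittable_error")
    return(unname(fill))
  }
  fill <- model$labeled_mean[feature]
  if (is.na(fill))
    gbm_abort(paste0("unfittable feature '", feature,
                     "': never observed among labeled sessions"),
              "gbm_unfittable_error")
  unname(fill)
}

#' Impute the missing features of a single session
#'
#' Applies the volume-conditioned rules to one row of a cohort table:
#' a missing feature measured over a region whose volume is exactly 0 is
#' filled with 1 (perfusion) or the responsive mean (diffusion,
#' spectroscopy); a missing feature over a region with positive volume is
#' filled with the labeled mean. Present values are never altered, and the
#' operation is idempotent.
#'
#' @param point a 1-row data frame conforming to the cohort layout.
#' @param model an [fit_imputer()] model.
#' @param schema a [gbm_schema()].
#' @return The row with every feature observed.
#' @export
impute_point <- function(point, model, schema = gbm_schema()) {
  stopifnot(is.data.frame(point), nrow(point) == 1L,
            inherits(model, "imputation_model"))
  for (f in schema$names) {
    if (is.na(point[[f]])) {
      if (f %in% schema$always_present)
        gbm_abort(paste0("always-present feature '", f, "' is missing"),
                  "gbm_always_present_error")
      point[[f]] <- .impute_value(f, point, model, schema)
    }
  }
  point
}

#' Impute every session of a cohort
#'
#' Applies [impute_point()] to all sessions (labeled and unlabeled). The
#' returned cohort has no missing feature values.
#'
#' @param cohort a `gbm_cohort`.
#' @param model an [fit_imputer()] model.
#' @return The fully observed `gbm_cohort`.
#' @export
impute_cohort <- function(cohort, model) {
  stopifnot(inherits(cohort, "gbm_cohort"), inherits(model, "imputation_model"))
  schema <- cohort$schema
  d <- cohort$data
  feats <- setdiff(schema$names, schema$always_present)
  unfittable <- character(0)
  for (f in feats) {
    miss <- which(is.na(d[[f]]))
    if (!length(miss)) next
    region <- schema$region[[f]]
    zero_vol <- if (is.na(region)) rep(FALSE, length(miss)) else
      d[[region_volume_feature(region)]][miss] == 0
    modality <- schema$modality[[f]]
    fill <- numeric(length(miss))
    # zero-volume branch
    if (modality == "perfusion") {
      fill[zero_vol] <- model$perfusion_fill
    } else if (any(zero_vol)) {
      rm_ <- model$responsive_mean[f]
      if (is.na(rm_)) { unfittable <- c(unfittable, f); next }
      fill[zero_vol] <- rm_
    }
    # positive-volume branch
    if (any(!zero_vol)) {
      lm_ <- model$labeled_mean[f]
      if (is.na(lm_)) { unfittable <- c(unfittable, f); next }
      fill[!zero_vol] <- lm_
    }
    d[[f]][miss] <- fill
  }
  if (length(unfittable))
    gbm_abort(paste0("unfittable feature(s): ",
                     paste(unique(unfittable), collapse = ", ")),
              "gbm_unfittable_error")
  cohort$data <- d
  cohort
}

#' Serialise / load an imputation model
#'
#' Writes the learned replacement values to a JSON file for audit.
#'
#' @param model an `imputation_model`.
#' @param path file path.
#' @return `write_imputation_model` returns `path` invisibly;
#'   `read_imputation_model` returns an `imputation_model`.
#' @export
write_imputation_model <- function(model, path) {
  stopifnot(inherits(model, "imputation_model"))
  jsonlite::write_json(
    list(responsive_mean = as.list(model$responsive_mean),
         labeled_mean = as.list(model$labeled_mean),
         perfusion_fill = model$perfusion_fill),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_imputation_model
#' @export
read_imputation_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(responsive_mean = unlist(x$responsive_mean) %||%
                   stats::setNames(numeric(0), character(0)),
                 labeled_mean = unlist(x$labeled_mean) %||%
                   stats::setNames(numeric(0), character(0)),
                 perfusion_fill = x$perfusion_fill),
            class = "imputation_model")
}
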