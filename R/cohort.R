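# Cohort container: one row per MRI session per patient, 27 feature columns,
# NA = missing. Labels are aligned to the session at which the clinical
# (RANO-based) decision was made: sessions at and after the decision carry the
# patient's decision class, earlier sessions are "unlabeled".

.COHORT_ID_COLS <- c("patient_id", "session_index", "decision_class",
                     "decision_session")
.LABEL_LEVELS <- c("progressive", "responsive", "unlabeled")
.CLASS_LEVELS <- c("progressive", "responsive")

#' Construct a longitudinal cohort
#'
#' Wraps a per-session feature table into a validated `gbm_cohort`. The table
#' must have one row per MRI session with the identifier columns
#' `patient_id`, `session_index`, `decision_class`, `decision_session`
#' followed by the 27 schema feature columns. `NA` entries mark missing
#' feature values; always-present features (volumes, resection flag, group
#' code) may never be `NA`.
#'
#' @param data a data frame as described above. Optional `offset` and `label`
#'   columns (as produced by [propagate_labels()]) are kept if present.
#' @param schema a [gbm_schema()].
#' @return An object of class `gbm_cohort`: a list with elements `schema` and
#'   `data` (the validated data frame, ordered by patient and session).
#' @export
as_cohort <- function(data, schema = gbm_schema()) {
  stopifnot(is.data.frame(data))
  validate_schema(schema)
  data <- as.data.frame(data)

  missing_cols <- setdiff(c(.COHORT_ID_COLS, schema$names), names(data))
  if (length(missing_cols))
    gbm_abort(paste0("feature table is missing column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "gbm_column_error")
  extra <- setdiff(names(data),
                   c(.COHORT_ID_COLS, schema$names, "offset", "label"))
  if (length(extra))
    gbm_abort(paste0("unknown column(s): ", paste(extra, collapse = ", ")),
              "gbm_column_error")

  data$patient_id <- as.character(data$patient_id)
  data$session_index <- as.integer(data$session_index)
  data$decision_session <- as.integer(data$decision_session)
  data$decision_class <- as.character(data$decision_class)
  for (f in schema$names) data[[f]] <- as.numeric(data[[f]])
  if ("offset" %in% names(data)) data$offset <- as.integer(data$offset)
  if ("label" %in% names(data)) {
    data$label <- as.character(data$label)
    bad <- !data$label %in% .LABEL_LEVELS
    if (any(bad))
      gbm_abort(paste0("invalid label(s): ",
                       paste(unique(data$label[bad]), collapse = ", ")),
                "gbm_label_error")
  }

  key <- paste(data$patient_id, data$session_index)
  if (anyDuplicated(key))
    gbm_abort(paste0("duplicate (patient, session) row(s): ",
                     paste(unique(key[duplicated(key)]), collapse = "; ")),
              "gbm_duplicate_error")

  bad_class <- !data$decision_class %in% .CLASS_LEVELS
  if (any(bad_class))
    gbm_abort(paste0("decision_class must be 'progressive' or 'responsive'; got: ",
                     paste(unique(data$decision_class[bad_class]), collapse = ", ")),
              "gbm_class_error")

  ap_na <- vapply(schema$always_present, function(f) anyNA(data[[f]]), NA)
  if (any(ap_na))
    gbm_abort(paste0("always-present feature(s) contain missing values: ",
                     paste(schema$always_present[ap_na], collapse = ", ")),
              "gbm_always_present_error")

  for (f in .VOLUME_FEATURES)
    if (any(data[[f]] < 0, na.rm = TRUE))
      gbm_abort(paste0("negative volume in ", f), "gbm_volume_error")

  for (pid in unique(data$patient_id)) {
    rows <- data[data$patient_id == pid, ]
    if (length(unique(rows$decision_class)) != 1L)
      gbm_abort(paste0("patient ", pid, " has more than one decision class"),
                "gbm_class_error")
    if (length(unique(rows$decision_session)) != 1L)
      gbm_abort(paste0("patient ", pid, " has more than one decision session"),
                "gbm_decision_error")
    if (!rows$decision_session[1] %in% rows$session_index)
      gbm_abort(paste0("decision_session of patient ", pid,
                       " is not among the patient's sessions"),
                "gbm_decision_error")
  }

  data <- data[order(data$patient_id, data$session_index), , drop = FALSE]
  rownames(data) <- NULL
  structure(list(schema = schema, data = data), class = "gbm_cohort")
}

#' @export
print.gbm_cohort <- function(x, ...) {
  d <- x$data
  cat(sprintf("<gbm_cohort> %d patients, %d sessions, %d features\n",
              length(unique(d$patient_id)), nrow(d), length(x$schema$names)))
  if ("label" %in% names(d)) {
    tab <- table(d$label)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  n_miss <- sum(is.na(d[, x$schema$names]))
  cat(sprintf("  missing cells: %d (%.1f%% of feature cells)\n",
              n_miss, 100 * n_miss / (nrow(d) * length(x$schema$names))))
  invisible(x)
}

#' Number of patients / sessions in a cohort
#' @param cohort a `gbm_cohort`.
#' @return integer count.
#' @export
n_patients <- function(cohort) length(unique(cohort$data$patient_id))

#' @rdname n_patients
#' @export
n_sessions <- function(cohort) nrow(cohort$data)

#' Propagate decision-aligned labels along each patient's timeline
#'
#' Computes, for every session, its signed offset from the decision session
#' (in ordinal session steps, not calendar time: offset 0 is the decision
#' session, negative offsets precede it) and assigns labels accordingly:
#' sessions at and after the decision carry the patient's decision class,
#' sessions before it are `"unlabeled"`. The operation is idempotent.
#'
#' @param cohort a `gbm_cohort`.
#' @return The cohort with `offset` and `label` columns filled in.
#' @export
propagate_labels <- function(cohort) {
  stopifnot(inherits(cohort, "gbm_cohort"))
  d <- cohort$data
  d$offset <- NA_integer_
  d$label <- NA_character_
  for (pid in unique(d$patient_id)) {
    idx <- which(d$patient_id == pid)
    sessions <- d$session_index[idx]          # already sorted
    dpos <- match(d$decision_session[idx[1]], sessions)
    offs <- seq_along(sessions) - dpos
    d$offset[idx] <- offs
    d$label[idx] <- ifelse(offs >= 0L, d$decision_class[idx[1]], "unlabeled")
  }
  cohort$data <- d
  cohort
}

has_labels <- function(cohort) {
  all(c("offset", "label") %in% names(cohort$data)) &&
    !anyNA(cohort$data$offset)
}

require_labels <- function(cohort) {
  if (!has_labels(cohort)) propagate_labels(cohort) else cohort
}

#' Restrict a cohort to sessions with a complete feature vector
#'
#' Keeps only sessions where every schema feature is observed; patients left
#' with no session are dropped entirely. Applying it twice is the same as
#' applying it once.
#'
#' @param cohort a `gbm_cohort`.
#' @return The filtered `gbm_cohort`.
#' @export
select_complete <- function(cohort) {
  stopifnot(inherits(cohort, "gbm_cohort"))
  feats <- cohort$schema$names
  keep <- stats::complete.cases(cohort$data[, feats, drop = FALSE])
  cohort$data <- cohort$data[keep, , drop = FALSE]
  rownames(cohort$data) <- NULL
  cohort
}

#' Restrict a cohort to a single imaging modality
#'
#' Drops all feature columns except the requested modality block. By default
#' the two always-present clinical features (resection flag, group code) are
#' retained alongside the modality columns; volumes are not (they form their
#' own feature category). `"all"` is the identity.
#'
#' @inheritParams modality_features
#' @param cohort a `gbm_cohort`.
#' @return A `gbm_cohort` whose schema and data are restricted to the chosen
#'   columns.
#' @export
modality_subset <- function(cohort, modality, keep_clinical = TRUE) {
  stopifnot(inherits(cohort, "gbm_cohort"))
  modality <- match.arg(modality,
                        c("all", "perfusion", "diffusion", "spectroscopy"))
  if (modality == "all") return(cohort)
  feats <- modality_features(cohort$schema, modality, keep_clinical)
  s <- cohort$schema
  s$names <- feats
  s$modality <- s$modality[feats]
  s$region <- s$region[feats]
  s$always_present <- intersect(s$always_present, feats)
  keep_cols <- c(.COHORT_ID_COLS, feats,
                 intersect(c("offset", "label"), names(cohort$data)))
  cohort$data <- cohort$data[, keep_cols, drop = FALSE]
  cohort$schema <- s
  cohort
}

#' Patients per decision-aligned time point
#'
#' Counts, for every offset present in the cohort, how many patients have a
#' session at that offset (each patient contributes at most one session per
#' offset). Labels must have been propagated.
#'
#' @param cohort a `gbm_cohort`.
#' @return A data frame with columns `offset` (integer, decreasing) and `n`
#'   (integer patient count); zero rows for an empty cohort.
#' @export
counts_per_offset <- function(cohort) {
  cohort <- require_labels(cohort)
  d <- cohort$data
  if (nrow(d) == 0L)
    return(data.frame(offset = integer(), n = integer()))
  tab <- table(d$offset)
  out <- data.frame(offset = as.integer(names(tab)), n = as.integer(tab))
  out[order(-out$offset), , drop = FALSE]
}

#' Read / write the feature-table CSV
#'
#' The on-disk format is a comma-separated UTF-8 table with a header row:
#' `patient_id`, `session_index`, `decision_class`, `decision_session`, then
#' the 27 feature columns in schema order (plus `offset` and `label` when
#' labels have been propagated). Empty cells denote missing values. Numeric
#' values are written with enough digits to round-trip exactly.
#'
#' @param path CSV file path.
#' @param schema a [gbm_schema()].
#' @param cohort a `gbm_cohort`.
#' @return `load_cohort` returns a validated `gbm_cohort`; `write_cohort`
#'   returns `path` invisibly.
#' @export
load_cohort <- function(path, schema = gbm_schema()) {
  raw <- readr::read_csv(path, na = "", col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  raw <- as.data.frame(raw)
  missing_cols <- setdiff(c(.COHORT_ID_COLS, schema$names), names(raw))
  if (length(missing_cols))
    gbm_abort(paste0("feature table is missing column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "gbm_column_error")
  for (col in setdiff(names(raw), c("patient_id", "decision_class", "label")))
    raw[[col]] <- as.numeric(raw[[col]])
  as_cohort(raw, schema)
}

#' @rdname load_cohort
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "gbm_cohort"))
  readr::write_csv(cohort$data, path, na = "", progress = FALSE)
  invisible(path)
}
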