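# Performance indices: per-time-point balanced error rate and its weighted
# aggregate (wBER). Offsets are measured in ordinal session steps from the
# clinical decision session (0 = decision, negative = before).

#' Balanced error rate of a set of predictions
#'
#' Mean of the two per-class misclassification rates (fraction of responsive
#' cases predicted progressive, and vice versa). When only one class occurs
#' in `truth`, the BER is the error rate of that class alone: the other
#' class's rate is an empty average and is dropped rather than counted as 0
#' or 0.5, so a single misclassified patient scores 1 and a single correctly
#' classified patient scores 0.
#'
#' @param truth,predicted equal-length vectors of class labels, each element
#'   `"progressive"` or `"responsive"`.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' balanced_error_rate(c("responsive", "progressive"), c("responsive", "progressive")) # 0
balanced_error_rate <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) == 0L)
    gbm_abort("balanced_error_rate needs at least one case", "gbm_metric_error")
  if (length(truth) != length(predicted))
    gbm_abort("truth and predicted must have equal length", "gbm_metric_error")
  bad <- !c(truth, predicted) %in% .CLASS_LEVELS
  if (any(bad))
    gbm_abort("labels must be 'progressive' or 'responsive'", "gbm_metric_error")
  rates <- vapply(.CLASS_LEVELS, function(cl) {
    in_cl <- truth == cl
    if (!any(in_cl)) return(NA_real_)
    mean(predicted[in_cl] != cl)
  }, numeric(1))
  mean(rates, na.rm = TRUE)
}

#' Temporal weight of a pre-decision time point
#'
#' Time points at or after the decision get full weight 1; a point `i`
#' sessions before the decision is down-weighted linearly with slope 0.5/11,
#' so the deepest offset observed in a typical follow-up (11 sessions before
#' the decision) still carries weight 0.5. The linear form is applied as-is
#' for `i > 11`.
#'
#' @param i non-negative integer (vectorised): number of sessions before the
#'   decision; `i = 0` encodes at-or-after the decision.
#' @return Numeric weight(s).
#' @export
#' @examples
#' temporal_weight(0)   # 1
#' temporal_weight(11)  # 0.5
temporal_weight <- function(i) {
  if (any(i < 0))
    gbm_abort("temporal_weight takes i >= 0 (sessions before the decision)",
              "gbm_metric_error")
  ifelse(i == 0, 1, 1 - (0.5 / 11) * i)
}

#' Per-offset balanced error rate series
#'
#' Container pairing each decision-aligned offset with its balanced error
#' rate and the number of patients contributing at that offset. Offsets with
#' no BER (no data) may carry `NA`.
#'
#' @param offset integer vector of signed offsets.
#' @param ber numeric vector in `[0, 1]`, `NA` allowed for empty offsets.
#' @param n integer vector of patient counts per offset.
#' @return An object of class `ber_series` (a data frame with columns
#'   `offset`, `ber`, `n`, ordered by decreasing offset).
#' @export
ber_series <- function(offset, ber, n) {
  stopifnot(length(offset) == length(ber), length(offset) == length(n))
  if (anyDuplicated(offset))
    gbm_abort("duplicate offsets in ber_series", "gbm_metric_error")
  if (any(ber < 0 | ber > 1, na.rm = TRUE))
    gbm_abort("ber values must lie in [0, 1]", "gbm_metric_error")
  if (any(!is.na(ber) & n < 1))
    gbm_abort("an offset with a BER value needs at least one patient",
              "gbm_metric_error")
  out <- data.frame(offset = as.integer(offset), ber = as.numeric(ber),
                    n = as.integer(n))
  out <- out[order(-out$offset), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ber_series", "data.frame")
  out
}

#' Weighted balanced error rate (wBER)
#'
#' Aggregates a per-offset BER series into a single number: the weighted mean
#' of the per-offset BERs, with weights the product of the temporal weight
#' ([temporal_weight()]) and a population weight proportional to the number
#' of patients observed at that offset. The population normaliser (total
#' patient count) cancels in the ratio, so only relative counts matter.
#' Offsets whose BER is `NA` contribute nothing.
#'
#' @param series a [ber_series()].
#' @return A number in `[0, 1]`.
#' @export
weighted_ber <- function(series) {
  stopifnot(inherits(series, "ber_series"))
  keep <- !is.na(series$ber)
  if (!any(keep))
    gbm_abort("weighted_ber: no offset carries a BER value", "gbm_metric_error")
  s <- series[keep, , drop = FALSE]
  w <- s$n * temporal_weight(pmax(0L, -s$offset))
  sum(w * s$ber) / sum(w)
}

# ---- offset labels ---------------------------------------------------------

#' Render and parse decision-aligned offset labels
#'
#' Offsets are printed in the conventional follow-up notation: `"L"` for the
#' decision session, `"L+2"` / `"L-3"` for sessions after / before it. The
#' parser also accepts spaced (`"L - 3"`) and Unicode-minus variants.
#'
#' @param offset integer vector.
#' @param label character vector of labels.
#' @return `format_offset_label` returns characters; `parse_offset_label`
#'   returns integers.
#' @export
format_offset_label <- function(offset) {
  offset <- as.integer(offset)
  ifelse(offset == 0L, "L",
         ifelse(offset > 0L, paste0("L+", offset), paste0("L-", -offset)))
}

#' @rdname format_offset_label
#' @export
parse_offset_label <- function(label) {
  x <- gsub("[[:space:]*]", "", label)
  x <- gsub("−|–", "-", x)   # unicode minus / en-dash
  out <- integer(length(x))
  is_l <- x == "L"
  m <- regmatches(x, regexec("^L([+-])([0-9]+)$", x))
  for (j in seq_along(x)) {
    if (is_l[j]) { out[j] <- 0L; next }
    if (length(m[[j]]) != 3L)
      gbm_abort(paste0("cannot parse offset label '", label[j], "'"),
                "gbm_label_error")
    out[j] <- as.integer(m[[j]][3]) * if (m[[j]][2] == "-") -1L else 1L
  }
  out
}

# ---- wBER from published-style tables --------------------------------------

#' Weighted BER from a per-offset BER table and a counts table
#'
#' Reproduces the summary row of a published per-time-point BER table. The
#' BER table is a CSV whose first column holds offset labels (`"L+5"` ...
#' `"L-11"`) and whose remaining columns hold one classifier each, with blank
#' cells at offsets that had no data. The counts table is a CSV with columns
#' `offset` (same labels) and `n` (patients at that offset).
#'
#' @param ber_table path to the BER CSV.
#' @param counts_table path to the counts CSV.
#' @return Named numeric vector: one wBER per classifier column (full
#'   precision; round to 3 decimals for table display).
#' @export
wber_from_tables <- function(ber_table, counts_table) {
  ber <- as.data.frame(readr::read_csv(ber_table, na = c("", "-"),
                                       col_types = readr::cols(.default = "c"),
                                       progress = FALSE))
  cnt <- as.data.frame(readr::read_csv(counts_table, na = "",
                                       col_types = readr::cols(.default = "c"),
                                       progress = FALSE))
  if (!all(c("offset", "n") %in% names(cnt)))
    gbm_abort("counts table needs columns 'offset' and 'n'", "gbm_column_error")
  offsets <- parse_offset_label(ber[[1]])
  cnt_off <- parse_offset_label(cnt$offset)
  missing_off <- setdiff(offsets, cnt_off)
  if (length(missing_off))
    gbm_abort(paste0("offset(s) missing from the counts table: ",
                     paste(format_offset_label(missing_off), collapse = ", ")),
              "gbm_label_error")
  n <- as.integer(cnt$n)[match(offsets, cnt_off)]
  classifiers <- names(ber)[-1]
  out <- vapply(classifiers, function(cl) {
    b <- as.numeric(ber[[cl]])
    if (all(is.na(b)))
      gbm_abort(paste0("BER column '", cl, "' is empty"), "gbm_metric_error")
    weighted_ber(ber_series(offsets, b, n))
  }, numeric(1))
  out
}
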