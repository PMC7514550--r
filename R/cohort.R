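#' Assemble a cohort feature matrix
#'
#' Stacks per-subject feature rows into an analysis-ready cohort table with
#' an age-decade label (`floor(age / 10) * 10`) and, optionally, per-feature
#' z-scoring. The scaling statistics (per-feature mean and sd) are stored in
#' the `"scaling"` attribute so that the same scale can be re-applied to a
#' surrogate cohort with [apply_scaling()]: original-vs-shuffled comparisons
#' must share one scale.
#'
#' @param features a tibble of feature rows (e.g. stacked
#'   [extract_features()] output) with an `age_years` column.
#' @param normalize z-score each feature column?
#' @return a tibble of class `hrv_cohort`; attribute `"normalized"` records
#'   the state, `"scaling"` the statistics used.
#' @export
build_cohort_matrix <- function(features, normalize = FALSE) {
  stopifnot(is.data.frame(features), "age_years" %in% names(features))
  out <- tibble::as_tibble(features)
  if (any(out$age_years < 18 | out$age_years > 89, na.rm = TRUE)) {
    rlang::warn("ages outside the 18-89 study range present; kept")
  }
  if (any(out$age_years < 20 & out$age_years >= 18, na.rm = TRUE)) {
    rlang::warn("ages 18-19 map to the 20s decade group")
  }
  out$decade <- pmax(20L, as.integer(floor(out$age_years / 10) * 10))
  cohort <- structure(out, class = c("hrv_cohort", class(tibble::tibble())),
                      normalized = FALSE, scaling = NULL)
  if (normalize) normalize_cohort(cohort) else cohort
}

cohort_feature_cols <- function(cohort) {
  intersect(hrv_feature_names(), names(cohort)[vapply(cohort, is.numeric, TRUE)])
}

#' Z-score the feature columns of a cohort
#'
#' @param cohort an `hrv_cohort`.
#' @param scaling optional scaling tibble (`feature`, `mean`, `sd`) computed
#'   on another cohort; when `NULL` the statistics are computed here.
#' @return the normalized cohort, with `"scaling"` attribute set.
#' @export
normalize_cohort <- function(cohort, scaling = NULL) {
  cols <- cohort_feature_cols(cohort)
  if (is.null(scaling)) {
    scaling <- tibble::tibble(
      feature = cols,
      mean = vapply(cols, function(c) mean(cohort[[c]], na.rm = TRUE), 0),
      sd = vapply(cols, function(c) stats::sd(cohort[[c]], na.rm = TRUE), 0))
  }
  for (j in seq_len(nrow(scaling))) {
    f <- scaling$feature[j]
    if (!f %in% names(cohort)) next
    s <- scaling$sd[j]
    cohort[[f]] <- if (is.na(s) || s == 0) cohort[[f]] * 0 else
      (cohort[[f]] - scaling$mean[j]) / s
  }
  attr(cohort, "normalized") <- TRUE
  attr(cohort, "scaling") <- scaling
  cohort
}

#' @rdname normalize_cohort
#' @export
apply_scaling <- function(cohort, scaling) normalize_cohort(cohort, scaling)

#' Cohort-wide feature extraction
#'
#' Maps [extract_features()] over a cohort tibble with a `series`
#' list-column (as produced by [generate_cohort()] or [read_cohort()]).
#'
#' @param cohort tibble with `series` list-column plus metadata.
#' @param ... passed to [extract_features()].
#' @return stacked feature tibble, one row per subject.
#' @export
cohort_features <- function(cohort, ...) {
  dplyr::bind_rows(lapply(cohort$series, extract_features, ...))
}
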