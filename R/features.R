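#' Canonical order of the 33 HRV features
#'
#' The fixed, documented column order used by [extract_features()] and every
#' cohort-level routine. Sign-pattern probabilities use underscore names
#' (`p_ad` is p(ad), etc.).
#'
#' @return character vector of length 33.
#' @export
hrv_feature_names <- function() {
  c("meanRR", "meanHR", "stdRR", "sd2", "total", "rVLF", "rLF", "rHF",
    "pNN50", "pNN20", "RMSSD", "sd1", "E3", "E2", "E1", "ST", "sTE",
    "nzero", "PSS", "p_ddd", "Eddd", "Eaaa", "p_aaa", "PAS", "Edad",
    "p_dad", "p_ada", "Eada", "PIP", "Ead", "p_ad", "p_da", "Eda")
}

#' The ten-feature preset for compact classification
#'
#' A named subset of the 33 features that carries most of the age signal in
#' whole-night recordings; see also [select_features_greedy()] for the
#' score-driven search that motivates presets of this kind.
#'
#' @return character vector of 10 feature names.
#' @export
hrv_best10_features <- function() {
  c("meanRR", "total", "sd2", "PAS", "PSS", "PIP", "Edad", "Eda",
    "p_ad", "p_ada")
}

#' Extract the 33-measure HRV feature vector of one series
#'
#' Composes the time-domain, Poincare, Lomb-Scargle, fragmentation and
#' entropic measures into a single row in the canonical order of
#' [hrv_feature_names()]. A failed measure never disappears silently: its
#' value is `NA` and its name is recorded in the `flags` column.
#'
#' @param series a preprocessed [rr_series()].
#' @param window provenance label (`"full"`, `"5min"`, ...).
#' @param segment segment index (provenance), if any.
#' @param surrogate surrogate replicate number (provenance), if any.
#' @param oversample Lomb-Scargle grid oversampling.
#' @return one-row tibble: 33 feature columns, then `subject_id`,
#'   `age_years`, `window`, `segment`, `surrogate`, `flags`.
#' @export
extract_features <- function(series, window = "full", segment = NA_integer_,
                             surrogate = NA_integer_, oversample = 5) {
  flags <- character()
  grab <- function(expr, cols) {
    tryCatch(expr, error = function(e) {
      flags <<- c(flags, cols)
      tibble::as_tibble(stats::setNames(as.list(rep(NA_real_, length(cols))), cols))
    })
  }
  td <- grab(time_domain(series),
             c("meanRR", "meanHR", "stdRR", "RMSSD", "pNN50", "pNN20"))
  pc <- grab(poincare(series), c("sd1", "sd2"))
  ls <- grab(lomb_scargle_bands(series, oversample = oversample),
             c("total", "rVLF", "rLF", "rHF"))
  ent_cols <- c("E1", "E2", "E3", "ST", "sTE",
                "Ead", "Eda", "Eada", "Edad", "Eaaa", "Eddd")
  frag_cols <- c("PIP", "PAS", "PSS", "p_ad", "p_da", "p_ada", "p_dad",
                 "p_aaa", "p_ddd", "nzero")
  pat <- grab({
    acts <- compute_actions(series)
    d2 <- pattern_counts(acts, 2)
    d3 <- pattern_counts(acts, 3)
    dplyr::bind_cols(entropy_set(acts), fragmentation(d2, d3, acts))
  }, c(ent_cols, frag_cols))
  row <- dplyr::bind_cols(td, pc, ls, pat)
  out <- row[, hrv_feature_names()]
  out$subject_id <- rr_subject(series)
  out$age_years <- rr_age(series)
  out$window <- window
  out$segment <- as.integer(segment)
  out$surrogate <- as.integer(surrogate)
  out$flags <- if (length(flags)) paste(unique(flags), collapse = ";") else NA_character_
  out
}

#' Feature vectors of all fixed-length segments of a recording
#'
#' @param series an [rr_series()]; a 240-min window with the default
#'   `length_min = 5` yields 48 rows indexed 0..47.
#' @param length_min segment length in minutes.
#' @param ... passed to [extract_features()].
#' @return tibble of per-segment feature rows (failures surface as flagged
#'   rows, never dropped).
#' @export
segment_features <- function(series, length_min = 5, ...) {
  segs <- segment_rr(series, length_min)
  dplyr::bind_rows(lapply(seq_along(segs), function(k) {
    extract_features(segs[[k]], window = sprintf("%gmin", length_min),
                     segment = k - 1L, ...)
  }))
}

#' Select the extreme segment by a physiological criterion
#'
#' Picks the segment row minimizing mean heart rate (a deep-sleep proxy) or
#' RR variability (a proxy for NREM-to-REM transitions). Ties break to the
#' earliest segment index.
#'
#' @param features a [segment_features()] tibble.
#' @param criterion `"min_meanHR"` or `"min_stdRR"`.
#' @return the selected one-row tibble.
#' @export
select_extreme_segment <- function(features,
                                   criterion = c("min_meanHR", "min_stdRR")) {
  criterion <- match.arg(criterion)
  col <- switch(criterion, min_meanHR = "meanHR", min_stdRR = "stdRR")
  v <- features[[col]]
  if (all(is.na(v))) {
    rlang::abort("criterion undefined for every segment (all flagged)",
                 class = "hrvdyn_validation_error")
  }
  features[which.min(replace(v, is.na(v), Inf)), , drop = FALSE]
}
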