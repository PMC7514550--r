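#' Select the low-heart-rate analysis window
#'
#' Operationalises the choice of the nocturnal rest period: the contiguous
#' window of the requested duration whose mean heart rate is minimal, found
#' by a sliding-window search over beat onset times. An input of exactly the
#' requested duration is returned unchanged.
#'
#' @param series an [rr_series()].
#' @param duration_min window length in minutes (default 240, i.e. 4 h).
#' @param stride_min stride of the sliding search in minutes.
#' @return the selected window as an `rr_series`.
#' @export
extract_analysis_window <- function(series, duration_min = 240, stride_min = 1) {
  total_min <- rr_duration_min(series)
  if (total_min < duration_min - 1e-9) {
    rlang::abort(sprintf("series covers %.1f min, need %.1f", total_min,
                         duration_min), class = "hrvdyn_length_error")
  }
  onset <- series$t_s - series$rr_ms / 1000   # beat onset times
  onset <- onset - onset[1]
  if (total_min <= duration_min + 1e-9) return(series)
  dur_s <- duration_min * 60
  starts <- seq(0, (total_min - duration_min) * 60, by = stride_min * 60)
  # mean HR over a window = mean of per-beat 60000/RR for beats starting in it
  hr <- 60000 / series$rr_ms
  best <- NULL; best_hr <- Inf
  for (s in starts) {
    sel <- onset >= s - 1e-9 & onset < s + dur_s - 1e-9
    if (sum(sel) < 2) next
    m <- mean(hr[sel])
    if (m < best_hr) { best_hr <- m; best <- sel }
  }
  out <- series[best, , drop = FALSE]
  out$gap_before[1] <- 0L
  rr_rebuild(out, series)
}

#' Fill 1-2-beat gaps with local medians
#'
#' Gaps of one or two missing beats are replaced by the median of the three
#' preceding and three following intervals; larger gaps are left flagged so
#' that no action or pattern window ever spans them. At a series boundary
#' with fewer than three neighbours on a side, the available neighbours are
#' used and a warning is emitted.
#'
#' @param series an [rr_series()].
#' @param max_gap largest gap (in missing beats) to fill; default 2.
#' @return an `rr_series` with small gaps imputed and a `fill_log` entry in
#'   its `meta` attribute.
#' @export
fill_small_gaps <- function(series, max_gap = 2) {
  gaps <- which(series$gap_before > 0L & series$gap_before <= max_gap)
  if (length(gaps) == 0) return(series)
  rr <- series$rr_ms; gap <- series$gap_before; t_s <- series$t_s
  pieces <- list(); prev <- 1L; log <- list()
  for (g in gaps) {
    k <- gap[g]
    lo <- rr[max(1, g - 3):(g - 1)]
    hi <- rr[g:min(length(rr), g + 2)]
    if (length(lo) < 3 || length(hi) < 3) {
      rlang::warn(sprintf("gap at beat %d has fewer than 3 neighbours on one side", g))
    }
    fill <- stats::median(c(lo, hi))
    pieces[[length(pieces) + 1]] <- tibble::tibble(
      rr_ms = c(rr[prev:(g - 1)], rep(fill, k)),
      t_s = c(t_s[prev:(g - 1)], t_s[g - 1] + cumsum(rep(fill, k)) / 1000),
      gap_before = c(gap[prev:(g - 1)], rep(0L, k)))
    log[[length(log) + 1]] <- list(beat = g, size = k, value = fill)
    prev <- g
  }
  pieces[[length(pieces) + 1]] <- tibble::tibble(
    rr_ms = rr[prev:length(rr)], t_s = t_s[prev:length(rr)],
    gap_before = replace(gap[prev:length(rr)], 1, 0L))
  out <- dplyr::bind_rows(pieces)
  res <- rr_rebuild(out, series)
  meta <- attr(res, "meta"); meta$fill_log <- c(meta$fill_log, log)
  attr(res, "meta") <- meta
  res
}

#' Split an RR series into consecutive fixed-length segments
#'
#' Beats are assigned to half-open windows `[k*L, (k+1)*L)` of their onset
#' time (0-based from the first beat's onset), so the segments partition the
#' input. A trailing partial window is dropped with a warning.
#'
#' @param series an [rr_series()].
#' @param length_min segment length in minutes (default 5).
#' @return a list of `rr_series`, one per complete segment. A 240-min window
#'   with the default length yields exactly 48.
#' @export
segment_rr <- function(series, length_min = 5) {
  onset <- series$t_s - series$rr_ms / 1000
  onset <- onset - onset[1]
  total_min <- rr_duration_min(series)
  n_seg <- floor(total_min / length_min + 1e-9)
  if (n_seg < 1) {
    rlang::abort("series shorter than one segment", class = "hrvdyn_length_error")
  }
  idx <- floor(onset / (length_min * 60))
  if (any(idx >= n_seg)) {
    rlang::warn(sprintf("dropping %d beat(s) in the trailing partial window",
                        sum(idx >= n_seg)))
  }
  lapply(seq_len(n_seg) - 1L, function(k) {
    seg <- series[idx == k, , drop = FALSE]
    seg$gap_before[1] <- 0L
    rr_rebuild(seg, series)
  })
}

#' Shuffle-surrogate of an RR series
#'
#' Returns a series whose intervals are a uniformly random permutation of
#' the input intervals. The interval distribution is preserved exactly while
#' every temporal pattern is destroyed; gap structure is dropped and the
#' surrogate is treated as contiguous. Deterministic given `seed`.
#'
#' @param series an [rr_series()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an `rr_series` surrogate.
#' @seealso [surrogate_ensemble()] for the ten-replicate convention.
#' @export
shuffle_surrogate <- function(series, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  rr <- series$rr_ms[sample.int(nrow(series))]
  res <- rr_series(rr, subject_id = rr_subject(series), age_years = rr_age(series),
                   delta = rr_delta(series),
                   meta = c(attr(series, "meta"), list(surrogate_seed = seed)))
  res
}

#' Ensemble of shuffle surrogates
#'
#' Generates `n` surrogates with seeds `seed + 0 .. seed + n - 1`;
#' surrogate-based statistics downstream average these replicates.
#'
#' @param series an [rr_series()].
#' @param n number of replicates (default 10).
#' @param seed base seed.
#' @return list of `rr_series`.
#' @export
surrogate_ensemble <- function(series, n = 10, seed = 1) {
  lapply(seq_len(n) - 1L, function(k) shuffle_surrogate(series, seed + k))
}
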