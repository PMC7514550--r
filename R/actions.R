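#' Map an RR series to its series of RR actions
#'
#' An action is the increment between consecutive-in-time RR intervals,
#' `dRR(n) = RR(n) - RR(n-1)`, computed only inside gap-free runs so that no
#' action spans an annotated discontinuity. Each action carries a symbol
#' (`d` deceleration for dRR > 0, `a` acceleration for dRR < 0, `0` for no
#' action) and the quantized integer index `i = dRR / delta`. Increments
#' beyond +/- `clip_ms` are clipped to the boundary, as part of signal
#' editing; clipping affects the action series only, never the stored RR
#' values.
#'
#' @param series an [rr_series()], ideally after [fill_small_gaps()].
#' @param clip_ms clipping bound for |dRR| in ms (default 300).
#' @return a tibble of class `rr_actions` with columns `drr_ms`, `symbol`,
#'   `index`, `run` (gap-free run id), `valid_pair`, `valid_triple` (whether
#'   the 2- and 3-action window starting here stays within one run), and
#'   attributes `delta` and `M` (the maximum absolute index).
#' @export
compute_actions <- function(series, clip_ms = 300) {
  delta <- rr_delta(series)
  n <- nrow(series)
  if (n < 2) {
    return(new_rr_actions(tibble::tibble(
      drr_ms = numeric(), symbol = character(), index = integer(),
      run = integer(), valid_pair = logical(), valid_triple = logical()),
      delta = delta, M = 0L, n_beats = n))
  }
  run_beat <- cumsum(c(1L, as.integer(series$gap_before[-1] > 0L)))
  keep <- run_beat[-1] == run_beat[-n]            # pair (n-1, n) contiguous
  drr <- diff(series$rr_ms)[keep]
  run <- run_beat[-1][keep]
  drr <- pmin(pmax(drr, -clip_ms), clip_ms)
  idx <- as.integer(round(drr / delta))
  sym <- ifelse(drr > 0, "d", ifelse(drr < 0, "a", "0"))
  m <- length(drr)
  same_next <- if (m >= 2) c(run[-1] == run[-m], FALSE) else rep(FALSE, m)
  same_next2 <- if (m >= 3) c(run[-(1:2)] == run[seq_len(m - 2)], FALSE, FALSE) else rep(FALSE, m)
  new_rr_actions(tibble::tibble(
    drr_ms = drr, symbol = sym, index = idx, run = run,
    valid_pair = same_next, valid_triple = same_next & same_next2),
    delta = delta, M = if (m) max(abs(idx)) else 0L, n_beats = n)
}

new_rr_actions <- function(df, delta, M, n_beats = NA_integer_) {
  structure(df, class = c("rr_actions", class(tibble::tibble())),
            delta = delta, M = as.integer(M), n_beats = n_beats)
}

#' @rdname rr_delta
#' @export
actions_M <- function(x) attr(x, "M")

#' @export
print.rr_actions <- function(x, ...) {
  cat(sprintf("<rr_actions> %d actions, delta=%.4g ms, M=%d\n",
              nrow(x), attr(x, "delta"), attr(x, "M")))
  NextMethod()
}
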