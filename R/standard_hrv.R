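#' Time-domain HRV measures
#'
#' `meanRR` is the mean interval; `meanHR` the mean of the instantaneous
#' per-beat rates 60000/RR (bpm), not 60000/meanRR; `stdRR` the sample
#' standard deviation. `RMSSD`, `pNN50` and `pNN20` are computed on
#' gap-free adjacent differences only, with the strict inequality
#' `|dRR| > x` for the pNN thresholds.
#'
#' @param series an [rr_series()] with at least 2 beats.
#' @return one-row tibble: `meanRR`, `meanHR`, `stdRR`, `RMSSD` (ms),
#'   `pNN50`, `pNN20` (percent).
#' @export
time_domain <- function(series) {
  if (nrow(series) < 2) {
    rlang::abort("need at least 2 beats", class = "hrvdyn_length_error")
  }
  d <- gapfree_diffs(series)
  if (length(d) == 0) {
    rlang::abort("no gap-free adjacent pair in series",
                 class = "hrvdyn_validation_error")
  }
  tibble::tibble(
    meanRR = mean(series$rr_ms),
    meanHR = mean(60000 / series$rr_ms),
    stdRR = stats::sd(series$rr_ms),
    RMSSD = sqrt(mean(d^2)),
    pNN50 = 100 * mean(abs(d) > 50),
    pNN20 = 100 * mean(abs(d) > 20))
}

# unclipped adjacent differences within gap-free runs
gapfree_diffs <- function(series) {
  n <- nrow(series)
  if (n < 2) return(numeric())
  keep <- series$gap_before[-1] == 0L
  diff(series$rr_ms)[keep]
}

#' Poincare-plot dispersion measures
#'
#' `sd1` is the dispersion perpendicular to the identity line of the
#' RR(n+1)-vs-RR(n) scatter, `sqrt(var(dRR)/2)` on gap-free pairs
#' (population variance), and `sd2` the dispersion along it,
#' `sqrt(2*var(RR) - sd1^2)`. A numerically negative `sd2^2` is clamped to
#' zero with a warning.
#'
#' @param series an [rr_series()] with at least 3 beats.
#' @return one-row tibble with `sd1` and `sd2` (ms).
#' @export
poincare <- function(series) {
  if (nrow(series) < 3) {
    rlang::abort("need at least 3 beats", class = "hrvdyn_length_error")
  }
  d <- gapfree_diffs(series)
  varp <- function(x) mean((x - mean(x))^2)
  sd1sq <- varp(d) / 2
  sd2sq <- 2 * stats::var(series$rr_ms) - sd1sq
  if (sd2sq < 0) {
    rlang::warn("sd2^2 negative from numerical error; clamped to 0")
    sd2sq <- 0
  }
  tibble::tibble(sd1 = sqrt(sd1sq), sd2 = sqrt(sd2sq))
}

#' Lomb-Scargle band powers of an RR series
#'
#' Computes the Lomb-Scargle periodogram of the (mean-removed, unwindowed)
#' RR values against their beat times, which handles the uneven sampling of
#' a tachogram natively, and integrates it over the standard bands:
#' VLF 0.003-0.04 Hz, LF 0.04-0.15 Hz, HF 0.15-0.4 Hz. Powers are rescaled
#' so that the trapezoidal integral over the full grid equals the variance
#' of the series, making `total` (ms^2) comparable to `stdRR^2`;
#' `total = VLF + LF + HF` and the relative powers are each band divided by
#' `total`.
#'
#' @param series an [rr_series()] covering at least 2 minutes.
#' @param oversample frequency-grid oversampling of the fundamental `1/T`
#'   (default 5).
#' @return one-row tibble with `total`, `rVLF`, `rLF`, `rHF` and the
#'   absolute band powers `vlf_ms2`, `lf_ms2`, `hf_ms2`; the periodogram
#'   itself is attached as attribute `"periodogram"` (tibble `freq`,
#'   `power`).
#' @export
lomb_scargle_bands <- function(series, oversample = 5) {
  t <- series$t_s
  y <- series$rr_ms
  T <- t[length(t)] - t[1]
  if (T < 120) {
    rlang::abort("need at least 2 min of data", class = "hrvdyn_length_error")
  }
  if (T < 1 / 0.003) {
    rlang::warn("duration shorter than one VLF cycle; VLF power unreliable")
  }
  f <- seq(0.003, 0.4, by = 1 / (oversample * T))
  p <- lomb_power(t, y - mean(y), f)
  varp <- mean((y - mean(y))^2)
  raw_total <- trapz(f, p)
  scale <- if (raw_total > 0) varp / raw_total else 0
  p <- p * scale
  band <- function(lo, hi) {
    sel <- f >= lo & f <= hi
    if (sum(sel) < 2) return(0)
    trapz(f[sel], p[sel])
  }
  vlf <- band(0.003, 0.04); lf <- band(0.04, 0.15); hf <- band(0.15, 0.4)
  total <- vlf + lf + hf
  out <- tibble::tibble(
    total = total,
    rVLF = if (total > 0) vlf / total else NA_real_,
    rLF = if (total > 0) lf / total else NA_real_,
    rHF = if (total > 0) hf / total else NA_real_,
    vlf_ms2 = vlf, lf_ms2 = lf, hf_ms2 = hf)
  attr(out, "periodogram") <- tibble::tibble(freq = f, power = p)
  out
}

# classic tau-shifted Lomb-Scargle power at frequencies f, y pre-centred.
# Uses the double-angle identities so each block needs one sin and one cos
# of the nf x n phase matrix; blocks bound memory on long recordings.
lomb_power <- function(t, y, f, block = 1024L) {
  n <- length(t)
  out <- numeric(length(f))
  for (b in seq(1, length(f), by = block)) {
    fb <- f[b:min(length(f), b + block - 1L)]
    wt <- outer(2 * pi * fb, t)              # nf x n
    swt <- sin(wt); cwt <- cos(wt)
    Sh <- as.vector(swt %*% y); Ch <- as.vector(cwt %*% y)
    S2 <- 2 * rowSums(swt * cwt)             # sum sin(2wt)
    C2 <- rowSums(cwt * cwt) - rowSums(swt * swt)
    theta2 <- atan2(S2, C2)                  # 2 w tau
    ct <- cos(theta2 / 2); st <- sin(theta2 / 2)
    yc <- Ch * ct + Sh * st                  # sum y cos(wt - w tau)
    ys <- Sh * ct - Ch * st
    proj <- (C2 * cos(theta2) + S2 * sin(theta2)) / 2
    cc <- n / 2 + proj                       # sum cos^2(wt - w tau)
    ss <- n / 2 - proj
    out[b:(b + length(fb) - 1L)] <-
      0.5 * (yc^2 / pmax(cc, 1e-12) + ys^2 / pmax(ss, 1e-12))
  }
  out
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
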