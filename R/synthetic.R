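#' Parameters of the synthetic RR-cohort generator
#'
#' Defaults emulate a nocturnal Holter-derived cohort: an age-dependent
#' baseline `987 - 0.850 * age` ms and target beat-to-beat variability
#' `115 - 0.651 * age` ms (floored at 15 ms), band-limited LF (0.10 Hz) and
#' HF (0.25 Hz) oscillations, AR(1) short-term noise, quantization to the
#' 7.8125 ms quantum of a 128 Hz recorder (which produces genuine
#' zero-actions), occasional 1-2-beat gaps, and 240-min duration.
#'
#' @param baseline_intercept,baseline_slope mean RR at age 0 (ms) and its
#'   slope (ms/year).
#' @param sd_intercept,sd_slope,sd_floor target RR standard deviation at age
#'   0 (ms), its slope (ms/year), and the floor (ms).
#' @param lf_freq,hf_freq oscillator frequencies (Hz).
#' @param lf_amp,hf_amp oscillator amplitudes (ms).
#' @param ar_coef AR(1) coefficient of the noise term, in (-1, 1).
#' @param delta recorder quantum (ms).
#' @param gap_rate expected gaps per hour.
#' @param duration_min recording length (minutes).
#' @param mode `"structured"` (oscillators + AR noise), `"iid"` (intervals
#'   drawn independently, hence exchangeable), or `"markov"` (quantized
#'   actions follow `markov_P` on index states `markov_states`).
#' @param markov_states,markov_P index states and first-order transition
#'   matrix for `mode = "markov"`.
#' @return a list of class `hrv_generator_params`.
#' @export
generator_params <- function(baseline_intercept = 987, baseline_slope = -0.850,
                             sd_intercept = 115, sd_slope = -0.651, sd_floor = 15,
                             lf_freq = 0.10, hf_freq = 0.25,
                             lf_amp = 25, hf_amp = 30,
                             ar_coef = 0.8, delta = 7.8125,
                             gap_rate = 1, duration_min = 240,
                             mode = c("structured", "iid", "markov"),
                             markov_states = -1:1,
                             markov_P = default_markov_P()) {
  mode <- match.arg(mode)
  stopifnot(lf_freq > 0, lf_freq < 0.5, hf_freq > 0, hf_freq < 0.5,
            abs(ar_coef) < 1, delta > 0, duration_min > 0)
  for (age in c(18, 89)) {
    if (max(sd_floor, sd_intercept + sd_slope * age) < 0) {
      rlang::abort("variability negative within the 18-89 age range",
                   class = "hrvdyn_validation_error")
    }
  }
  structure(as.list(environment()), class = "hrv_generator_params")
}

default_markov_P <- function() {
  matrix(c(0.50, 0.20, 0.30,
           0.30, 0.40, 0.30,
           0.30, 0.20, 0.50), 3, 3, byrow = TRUE)
}

#' Generate one synthetic RR-interval subject
#'
#' In `structured` mode the series is
#' `RR(n) = baseline(age) + lf_amp sin(2 pi lf_freq t + phi1) +
#' hf_amp sin(2 pi hf_freq t + phi2) + AR(1) noise`, with the noise variance
#' chosen so the series hits the age-dependent target variability, beat
#' times self-consistent with the intervals, values quantized to the
#' recorder quantum and 1-2-beat gaps injected at `gap_rate`. Times are
#' obtained by a two-pass scheme: a first pass from baseline plus noise
#' fixes the oscillator phases (their bounded contribution to elapsed time
#' is negligible), a second pass recomputes times from the final quantized
#' intervals.
#'
#' @param age age in years.
#' @param params a [generator_params()] list.
#' @param seed integer seed (deterministic given the seed).
#' @return an [rr_series()].
#' @export
generate_subject <- function(age, params = generator_params(), seed = 1) {
  p <- params
  base <- p$baseline_intercept + p$baseline_slope * age
  if (base <= 0) {
    rlang::abort("parameters imply non-positive baseline RR",
                 class = "hrvdyn_validation_error")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  dur_s <- p$duration_min * 60
  n <- ceiling(dur_s / (base / 1000)) + 50L
  rr <- switch(p$mode,
    structured = {
      target_sd <- max(p$sd_floor, p$sd_intercept + p$sd_slope * age)
      osc_var <- (p$lf_amp^2 + p$hf_amp^2) / 2
      noise_sd <- sqrt(max(target_sd^2 - osc_var, 25))
      e <- as.numeric(stats::filter(stats::rnorm(n), p$ar_coef, "recursive"))
      e <- e * noise_sd / stats::sd(e)
      t1 <- cumsum(base + e) / 1000             # first-pass beat times (s)
      phi <- stats::runif(2, 0, 2 * pi)
      base + e +
        p$lf_amp * sin(2 * pi * p$lf_freq * t1 + phi[1]) +
        p$hf_amp * sin(2 * pi * p$hf_freq * t1 + phi[2])
    },
    iid = {
      target_sd <- max(p$sd_floor, p$sd_intercept + p$sd_slope * age)
      stats::rnorm(n, base, target_sd)
    },
    markov = {
      idx <- simulate_markov_chain(n, p$markov_states, p$markov_P)
      base + cumsum(idx * p$delta)
    })
  rr <- round(rr / p$delta) * p$delta
  low <- rr < p$delta
  if (any(low)) {
    rlang::warn(sprintf("%d generated intervals fell below one quantum; floored", sum(low)))
    rr[low] <- p$delta
  }
  keep <- (cumsum(rr) - rr) / 1000 < dur_s   # beat onset inside the window
  rr <- rr[keep]
  t_full <- cumsum(rr) / 1000
  keep_i <- seq_along(rr)
  n_gaps <- stats::rpois(1, p$gap_rate * p$duration_min / 60)
  if (n_gaps > 0 && length(rr) > 40) {
    pos <- sort(sample(20:(length(rr) - 20), n_gaps))
    sizes <- sample(1:2, n_gaps, replace = TRUE)
    drop <- unique(unlist(mapply(function(q, s) q:(q + s - 1), pos, sizes,
                                 SIMPLIFY = FALSE)))
    keep_i <- setdiff(seq_along(rr), drop)
  }
  # per retained beat: how many beats were dropped since the previous one
  dcum <- cumsum(!seq_along(rr) %in% keep_i)
  prev <- c(0L, keep_i[-length(keep_i)])
  gap <- dcum[keep_i] - ifelse(prev == 0L, 0L, dcum[pmax(prev, 1L)])
  rr_series(rr[keep_i], gap_before = gap, t_s = t_full[keep_i],
            subject_id = sprintf("synt%04d", seed), age_years = age,
            delta = p$delta, meta = list(generator = p$mode, seed = seed))
}

simulate_markov_chain <- function(n, states, P) {
  stopifnot(nrow(P) == length(states), ncol(P) == length(states),
            all(abs(rowSums(P) - 1) < 1e-9))
  out <- integer(n)
  s <- sample.int(length(states), 1)
  u <- stats::runif(n)
  cp <- t(apply(P, 1, cumsum))
  for (j in seq_len(n)) {
    s <- findInterval(u[j], cp[s, ], left.open = TRUE) + 1L
    out[j] <- s
  }
  states[out]
}

#' Generate a synthetic action series directly
#'
#' Produces the quantized action (increment) series itself, bypassing
#' interval generation: `mode = "iid"` draws the indices independently and
#' identically from `probs` (default a discretized Gaussian, sd 1.5 quanta,
#' truncated to -4..4) so that the analytic independence limits `ST = E1`,
#' `sTE = 0`, `E2 = 2 E1` hold; `mode = "markov"` runs a first-order chain
#' on `states` with transition matrix `transition`; `mode = "markov2"` runs
#' a second-order chain where the next state repeats the state two steps
#' back with probability `repeat_prob` (a memory that no first-order model
#' captures, so `sTE > 0`).
#'
#' @param n number of actions.
#' @param mode `"iid"`, `"markov"` or `"markov2"`.
#' @param probs named or plain vector of probabilities over `states`
#'   (iid mode).
#' @param states integer index states.
#' @param transition first-order transition matrix (markov mode).
#' @param repeat_prob probability of repeating the lag-2 state (markov2).
#' @param delta quantum in ms used to scale `drr_ms`.
#' @param seed integer seed.
#' @return an `rr_actions` tibble (single gap-free run).
#' @export
simulate_action_series <- function(n, mode = c("iid", "markov", "markov2"),
                                   probs = NULL, states = NULL,
                                   transition = default_markov_P(),
                                   repeat_prob = 0.7,
                                   delta = 7.8125, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  idx <- switch(mode,
    iid = {
      if (is.null(probs)) {
        states <- states %||% (-4:4)
        probs <- iid_action_probs(states = states)
      } else {
        states <- states %||% (seq_along(probs) - (length(probs) + 1) %/% 2)
        probs <- probs / sum(probs)
      }
      sample(states, n, replace = TRUE, prob = probs)
    },
    markov = {
      states <- states %||% (-1:1)
      simulate_markov_chain(n, states, transition)
    },
    markov2 = {
      states <- states %||% (-1:1)
      m <- length(states)
      out <- integer(n)
      out[1:2] <- sample.int(m, 2, replace = TRUE)
      u <- stats::runif(n)
      for (j in 3:n) {
        if (u[j] < repeat_prob) {
          out[j] <- out[j - 2]
        } else {
          out[j] <- sample(setdiff(seq_len(m), out[j - 2]), 1)
        }
      }
      states[out]
    })
  idx <- as.integer(idx)
  new_rr_actions(tibble::tibble(
    drr_ms = idx * delta,
    symbol = ifelse(idx > 0, "d", ifelse(idx < 0, "a", "0")),
    index = idx, run = 1L,
    valid_pair = c(rep(TRUE, n - 1), FALSE),
    valid_triple = c(rep(TRUE, max(n - 2, 0)), rep(FALSE, min(n, 2)))),
    delta = delta, M = max(abs(idx)), n_beats = n + 1L)
}

#' Discretized-Gaussian action distribution
#'
#' The default index distribution of the iid action mode: proportional to a
#' Gaussian density with the given sd (in quanta), truncated to `states`.
#'
#' @param sd standard deviation in index units.
#' @param states integer support.
#' @return probability vector over `states`.
#' @export
iid_action_probs <- function(sd = 1.5, states = -4:4) {
  p <- stats::dnorm(states, 0, sd)
  p / sum(p)
}

#' Generate a synthetic cohort of RR recordings
#'
#' Ages are drawn uniformly within each decade; each subject gets its own
#' seed offset so any subject is reproducible in isolation.
#'
#' @param decade_sizes named integer vector, decade label (20..80) to
#'   subject count. The default reproduces a 181-subject, 7-decade cohort
#'   (30, 21, 33, 31, 27, 22, 17 subjects for the 20s..80s).
#' @param params a [generator_params()] list.
#' @param seed master seed.
#' @return a tibble with columns `subject_id`, `age_years`, `decade` and a
#'   list-column `series` of [rr_series()] objects.
#' @export
generate_cohort <- function(decade_sizes = c(`20` = 30, `30` = 21, `40` = 33,
                                             `50` = 31, `60` = 27, `70` = 22,
                                             `80` = 17),
                            params = generator_params(), seed = 1) {
  decade_sizes <- decade_sizes[decade_sizes > 0]
  if (length(decade_sizes) == 0 || sum(decade_sizes) == 0) {
    rlang::abort("empty cohort", class = "hrvdyn_validation_error")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  decades <- rep(as.integer(names(decade_sizes)), decade_sizes)
  ages <- as.integer(floor(stats::runif(length(decades), decades, decades + 10)))
  tibble::tibble(
    subject_id = sprintf("synt%04d", seed + seq_along(ages)),
    age_years = ages,
    decade = decades,
    series = lapply(seq_along(ages), function(j) {
      generate_subject(ages[j], params, seed = seed + j)
    }))
}

#' Write a generated cohort to per-subject CSV files plus a manifest
#'
#' @param cohort a [generate_cohort()] tibble.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s.csv", cohort$subject_id)
  purrr::walk2(cohort$series, files,
               function(s, f) write_rr_series(s, file.path(dir, f)))
  manifest <- tibble::tibble(subject_id = cohort$subject_id,
                             age_years = cohort$age_years, file = files)
  mp <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mp, progress = FALSE)
  invisible(mp)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest path to the manifest CSV (`subject_id`, `age_years`,
#'   `file`).
#' @return a tibble like [generate_cohort()]'s.
#' @export
read_cohort <- function(manifest) {
  man <- readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  dir <- dirname(manifest)
  tibble::tibble(
    subject_id = as.character(man$subject_id),
    age_years = as.integer(man$age_years),
    decade = as.integer(floor(man$age_years / 10) * 10),
    series = purrr::pmap(man, function(subject_id, age_years, file, ...) {
      read_rr_series(file.path(dir, file), subject_id = as.character(subject_id),
                     age_years = age_years)
    }))
}
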