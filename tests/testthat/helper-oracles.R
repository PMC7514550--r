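`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracles for the symbolic-dynamics layer. These
# deliberately use plain loops, string keys and table() so they share no code
# path with the package implementation.

naive_pattern_table <- function(actions, k) {
  i <- actions$index
  r <- actions$run
  n <- length(i)
  keys <- character(0)
  if (n >= k) {
    for (s in seq_len(n - k + 1)) {
      if (any(r[s:(s + k - 1)] != r[s])) next
      keys <- c(keys, paste(i[s:(s + k - 1)], collapse = ","))
    }
  }
  table(keys)
}

naive_entropy <- function(tab) {
  p <- as.numeric(tab) / sum(tab)
  -sum(p * log(p))
}

# partial entropy restricted to a sign pattern, from the naive table
naive_partial <- function(tab, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  tot <- sum(tab)
  acc <- 0
  for (key in names(tab)) {
    ii <- as.integer(strsplit(key, ",")[[1]])
    ok <- TRUE
    for (j in seq_along(pat)) {
      if (pat[j] == "a" && ii[j] >= 0) ok <- FALSE
      if (pat[j] == "d" && ii[j] <= 0) ok <- FALSE
    }
    if (ok) {
      p <- tab[[key]] / tot
      acc <- acc - p * log(p)
    }
  }
  acc
}

naive_octant_mass <- function(tab, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  tot <- sum(tab)
  acc <- 0
  for (key in names(tab)) {
    ii <- as.integer(strsplit(key, ",")[[1]])
    ok <- TRUE
    for (j in seq_along(pat)) {
      if (pat[j] == "a" && ii[j] >= 0) ok <- FALSE
      if (pat[j] == "d" && ii[j] <= 0) ok <- FALSE
    }
    if (ok) acc <- acc + tab[[key]] / tot
  }
  acc
}

# build a consistent rr_actions tibble from explicit indices and runs
actions_from_indices <- function(idx, run = rep(1L, length(idx)), delta = 8) {
  idx <- as.integer(idx)
  run <- as.integer(run)
  m <- length(idx)
  same_next <- if (m >= 2) c(run[-1] == run[-m], FALSE) else rep(FALSE, m)
  same_next2 <- if (m >= 3) c(run[-(1:2)] == run[seq_len(m - 2)], FALSE, FALSE) else rep(FALSE, m)
  hrvdyn:::new_rr_actions(tibble::tibble(
    drr_ms = idx * delta,
    symbol = ifelse(idx > 0, "d", ifelse(idx < 0, "a", "0")),
    index = idx, run = run,
    valid_pair = same_next, valid_triple = same_next & same_next2),
    delta = delta, M = if (m) max(abs(idx)) else 0L)
}

# random short action series with occasional run breaks, for property tests
random_actions <- function(n, M = 3, n_runs = 1) {
  actions_from_indices(sample(-M:M, n, replace = TRUE),
                       sort(sample(seq_len(n_runs), n, replace = TRUE)))
}

# convert a pattern_counts() tibble to the oracle's key/count representation
dist_as_keys <- function(dist) {
  k <- attr(dist, "k")
  keys <- do.call(paste, c(lapply(seq_len(k), function(j) dist[[paste0("i", j)]]),
                           sep = ","))
  stats::setNames(dist$n, keys)
}

# build an rr_series from raw vectors without going through the generator
make_series <- function(rr, gap = 0L, delta = NULL, age = NA_integer_) {
  rr_series(rr, gap_before = gap, delta = delta, subject_id = "fix",
            age_years = age)
}
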