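#' Empirical pattern distribution over k-tuples of quantized actions
#'
#' Counts every gap-free window of `k` consecutive quantized action indices,
#' the empirical measure on the pattern space of single actions (k = 1),
#' action pairs (k = 2) or action triples (k = 3). Windows that would cross
#' an annotated gap are excluded.
#'
#' @param actions an [compute_actions()] result (or any tibble with `index`
#'   and `run` columns).
#' @param k pattern order, 1, 2 or 3.
#' @return a tibble of class `pattern_dist` with index columns `i1..ik`,
#'   counts `n` and probabilities `p`, plus attributes `k`, `total` and `M`.
#' @examples
#' a <- simulate_action_series(100, seed = 1)
#' pattern_counts(a, 2)
#' @export
pattern_counts <- function(actions, k) {
  stopifnot(k %in% 1:3)
  i <- actions$index
  r <- actions$run
  m <- length(i)
  if (m < k) {
    rlang::abort("fewer contiguous actions than the pattern order",
                 class = "hrvdyn_empty_distribution")
  }
  start <- seq_len(m - k + 1)
  ok <- rep(TRUE, length(start))
  if (k >= 2) ok <- ok & r[start] == r[start + 1]
  if (k >= 3) ok <- ok & r[start] == r[start + 2]
  if (!any(ok)) {
    rlang::abort("no gap-free window of the requested order",
                 class = "hrvdyn_empty_distribution")
  }
  start <- start[ok]
  cols <- stats::setNames(
    lapply(seq_len(k) - 1L, function(o) i[start + o]),
    paste0("i", seq_len(k)))
  d <- dplyr::count(tibble::as_tibble(cols),
                    dplyr::across(dplyr::everything()), name = "n")
  d$p <- d$n / sum(d$n)
  structure(d, class = c("pattern_dist", class(tibble::tibble())),
            k = k, total = sum(d$n),
            M = attr(actions, "M") %||% max(abs(i)))
}

#' Shannon entropy of a pattern distribution (nats)
#'
#' `-sum p log p` over the observed patterns, natural logarithm, with the
#' convention `0 log 0 = 0`. Probabilities are maximum-likelihood
#' frequencies; no pseudocounts or bias correction are applied.
#'
#' @param dist a [pattern_counts()] result.
#' @return entropy in nats.
#' @export
shannon_entropy <- function(dist) {
  p <- dist$p
  if (length(p) == 0 || abs(sum(p) - 1) > 1e-9) {
    rlang::abort("distribution empty or not normalized",
                 class = "hrvdyn_empty_distribution")
  }
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Transition-rate entropy and self-transfer entropy
#'
#' From the pattern entropies E1 <= E2 <= E3 of one action series:
#' `ST = E2 - E1`, the conditional entropy of the next action given the
#' current one (the entropy rate of a first-order Markov model of the
#' actions), and `sTE = 2*E2 - E1 - E3`, the conditional mutual information
#' between an action and the action two steps back given the intervening
#' one. For a series of independent actions `ST = E1` and `sTE = 0`; both
#' quantities are nonnegative for true distributions.
#'
#' @param E1,E2,E3 entropies in nats of the order-1, 2, 3 pattern spaces.
#' @param tol tolerance for the ordering check. Plug-in estimates of E1 and
#'   E2 come from slightly different window sets, so near-deterministic
#'   series can violate the ordering by O(1/N); the default absorbs that.
#' @return a tibble with columns `ST` and `sTE` (nats).
#' @export
dynamic_landscape <- function(E1, E2, E3, tol = 1e-6) {
  if (E1 > E2 + tol || E2 > E3 + tol) {
    rlang::abort("entropy ordering E1 <= E2 <= E3 violated",
                 class = "hrvdyn_validation_error")
  }
  tibble::tibble(ST = E2 - E1, sTE = 2 * E2 - E1 - E3)
}

#' Partial entropy of one sign pattern
#'
#' The Shannon-sum contribution `-sum p log p` restricted to tuples whose
#' component signs match the given acceleration/deceleration pattern
#' (`a` = negative index, `d` = positive index; components with index 0 are
#' excluded). No renormalization is applied, so the partial entropies of the
#' disjoint sign octants, together with the zero-containing terms, sum
#' exactly to the full entropy of the space.
#'
#' @param dist a [pattern_counts()] result.
#' @param sign_pattern character like `"ad"` or `c("d","a","d")`, of the
#'   same length as the pattern order of `dist`.
#' @return partial entropy in nats.
#' @export
partial_entropy <- function(dist, sign_pattern) {
  pat <- if (length(sign_pattern) == 1) strsplit(sign_pattern, "")[[1]] else sign_pattern
  k <- attr(dist, "k")
  if (length(pat) != k) {
    rlang::abort(sprintf("pattern length %d does not match order %d",
                         length(pat), k), class = "hrvdyn_validation_error")
  }
  if (!all(pat %in% c("a", "d"))) {
    rlang::abort("sign pattern components must be 'a' or 'd'",
                 class = "hrvdyn_validation_error")
  }
  sel <- rep(TRUE, nrow(dist))
  for (j in seq_len(k)) {
    ij <- dist[[paste0("i", j)]]
    sel <- sel & if (pat[j] == "a") ij < 0 else ij > 0
  }
  p <- dist$p[sel]
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log(p))
}

#' Heart-rate fragmentation indices
#'
#' Octant masses of the pair and triple pattern spaces and the derived
#' percentages: percent of inflection points `PIP = (p_ad + p_da) * 100`,
#' percent of alternation segments `PAS = (p_ada + p_dad) * 100`, and
#' percent of short segments `PSS = (1 - p_aaa - p_ddd) * 100` (implemented
#' exactly in this printed form). Octant sums run over strictly signed
#' indices, so zero-containing patterns fall in the complement; the fraction
#' of zero actions is reported as `nzero`.
#'
#' @param dist2,dist3 order-2 and order-3 [pattern_counts()] of the same
#'   action series.
#' @param symbols the action symbols: an `rr_actions` object or its
#'   `symbol` column, used only for `nzero`.
#' @return one-row tibble with `PIP`, `PAS`, `PSS` (percent), the six octant
#'   probabilities `p_ad`, `p_da`, `p_ada`, `p_dad`, `p_aaa`, `p_ddd`, and
#'   `nzero`.
#' @export
fragmentation <- function(dist2, dist3, symbols) {
  if (attr(dist2, "k") != 2 || attr(dist3, "k") != 3) {
    rlang::abort("need order-2 and order-3 distributions",
                 class = "hrvdyn_validation_error")
  }
  if (!identical(attr(dist2, "M"), attr(dist3, "M"))) {
    rlang::abort("pattern spaces have mismatched index bound M",
                 class = "hrvdyn_validation_error")
  }
  if (inherits(symbols, "rr_actions") || is.data.frame(symbols)) {
    symbols <- symbols$symbol
  }
  oct2 <- function(s1, s2) {
    sel <- (if (s1 == "a") dist2$i1 < 0 else dist2$i1 > 0) &
           (if (s2 == "a") dist2$i2 < 0 else dist2$i2 > 0)
    sum(dist2$p[sel])
  }
  oct3 <- function(s1, s2, s3) {
    sgn <- function(col, s) if (s == "a") col < 0 else col > 0
    sum(dist3$p[sgn(dist3$i1, s1) & sgn(dist3$i2, s2) & sgn(dist3$i3, s3)])
  }
  p_ad <- oct2("a", "d"); p_da <- oct2("d", "a")
  p_ada <- oct3("a", "d", "a"); p_dad <- oct3("d", "a", "d")
  p_aaa <- oct3("a", "a", "a"); p_ddd <- oct3("d", "d", "d")
  tibble::tibble(
    PIP = (p_ad + p_da) * 100,
    PAS = (p_ada + p_dad) * 100,
    PSS = (1 - p_aaa - p_ddd) * 100,
    p_ad = p_ad, p_da = p_da, p_ada = p_ada, p_dad = p_dad,
    p_aaa = p_aaa, p_ddd = p_ddd,
    nzero = mean(symbols == "0"))
}

#' Full entropic characterisation of an action series
#'
#' Convenience wrapper computing the order-1..3 pattern distributions, their
#' entropies `E1`, `E2`, `E3`, the dynamic-landscape pair `ST`, `sTE`, and
#' the six partial entropies `Ead`, `Eda`, `Eada`, `Edad`, `Eaaa`, `Eddd`.
#'
#' @param actions an [compute_actions()] or [simulate_action_series()]
#'   result.
#' @return one-row tibble with the eleven entropic measures (nats).
#' @export
entropy_set <- function(actions) {
  d1 <- pattern_counts(actions, 1)
  d2 <- pattern_counts(actions, 2)
  d3 <- pattern_counts(actions, 3)
  E1 <- shannon_entropy(d1); E2 <- shannon_entropy(d2); E3 <- shannon_entropy(d3)
  dl <- dynamic_landscape(E1, E2, E3)
  tibble::tibble(
    E1 = E1, E2 = E2, E3 = E3, ST = dl$ST, sTE = dl$sTE,
    Ead = partial_entropy(d2, "ad"), Eda = partial_entropy(d2, "da"),
    Eada = partial_entropy(d3, "ada"), Edad = partial_entropy(d3, "dad"),
    Eaaa = partial_entropy(d3, "aaa"), Eddd = partial_entropy(d3, "ddd"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
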