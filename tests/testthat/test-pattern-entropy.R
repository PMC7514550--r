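test_that("compute_actions applies the sign rule, quantization, clipping and gap exclusion", {
  s <- make_series(c(800, 808, 808), delta = 8)
  a <- compute_actions(s)
  expect_equal(a$drr_ms, c(8, 0))
  expect_equal(a$symbol, c("d", "0"))
  expect_equal(a$index, c(1L, 0L))
  expect_equal(actions_M(a), 1L)

  # clipping at +/- 300 ms affects the action, not the stored intervals
  s2 <- make_series(c(700, 1050), delta = 1)
  a2 <- compute_actions(s2)
  expect_equal(a2$drr_ms, 300)
  expect_equal(s2$rr_ms, c(700, 1050))
  a2n <- compute_actions(make_series(c(1050, 700), delta = 1))
  expect_equal(a2n$drr_ms, -300)

  # no action or pattern spans a gap
  s3 <- make_series(c(800, 810, 900, 905), gap = c(0, 0, 1, 0), delta = 5)
  a3 <- compute_actions(s3)
  expect_equal(nrow(a3), 2)
  expect_equal(a3$drr_ms, c(10, 5))
  expect_false(any(a3$valid_pair))
  expect_error(pattern_counts(a3, 2), class = "hrvdyn_empty_distribution")

  expect_equal(nrow(compute_actions(make_series(800))), 0)
})

test_that("action count equals beats minus one per gap-free run", {
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    gap <- integer(n)
    gap[sample(2:n, sample(0:3, 1))] <- sample(1:3, 1)
    s <- make_series(800 + 8 * sample(0:20, n, TRUE), gap = gap, delta = 8)
    a <- compute_actions(s)
    n_runs <- 1 + sum(gap > 0)
    expect_equal(nrow(a), n - n_runs)
  }
})

test_that("pattern_counts matches hand-enumerated examples", {
  a <- actions_from_indices(c(1, -1, 1, -1))
  d2 <- pattern_counts(a, 2)
  expect_equal(attr(d2, "total"), 3)
  expect_equal(d2$p[d2$i1 == 1 & d2$i2 == -1], 2 / 3)
  expect_equal(d2$p[d2$i1 == -1 & d2$i2 == 1], 1 / 3)

  a1 <- actions_from_indices(c(2, 2, 2))
  d1 <- pattern_counts(a1, 1)
  expect_equal(d1$p, 1)
  expect_equal(d1$i1, 2L)
})

test_that("shannon_entropy agrees with closed forms and the naive oracle", {
  a <- actions_from_indices(rep(c(-2, -1, 1, 2), 10))
  expect_equal(shannon_entropy(pattern_counts(a, 1)), log(4), tolerance = 1e-12)
  a0 <- actions_from_indices(rep(3, 5))
  expect_equal(shannon_entropy(pattern_counts(a0, 1)), 0)
  set.seed(42)
  for (rep in 1:10) {
    a <- random_actions(sample(20:100, 1), M = 3, n_runs = sample(1:3, 1))
    for (k in 1:3) {
      tab <- naive_pattern_table(a, k)
      if (length(tab) == 0) next
      expect_equal(shannon_entropy(pattern_counts(a, k)), naive_entropy(tab),
                   tolerance = 1e-12)
    }
  }
})

test_that("dynamic landscape obeys the independence and periodicity limits", {
  # iid actions: ST -> E1 and sTE -> 0
  a <- simulate_action_series(5e4, "iid", seed = 7)
  es <- entropy_set(a)
  expect_lt(abs(es$ST - es$E1), 0.01)
  expect_lt(abs(es$sTE), 0.01)
  expect_equal(es$E2 / es$E1, 2, tolerance = 0.01)

  # deterministic period-2 alternation: every entropy ~ ln 2, ST = sTE ~ 0
  ap <- actions_from_indices(rep(c(1, -1), 500))
  esp <- entropy_set(ap)
  expect_equal(esp$E1, log(2), tolerance = 1e-5)
  expect_lt(abs(esp$ST), 1e-3)
  expect_lt(abs(esp$sTE), 1e-3)

  expect_error(dynamic_landscape(2, 1, 3), class = "hrvdyn_validation_error")
})

test_that("first-order Markov actions: ST matches the analytic entropy rate, sTE vanishes", {
  P <- matrix(c(0.6, 0.1, 0.3,
                0.25, 0.5, 0.25,
                0.3, 0.1, 0.6), 3, 3, byrow = TRUE)
  a <- simulate_action_series(1e5, "markov", transition = P, seed = 3)
  es <- entropy_set(a)
  # analytic entropy rate: -sum_i pi_i sum_j P_ij log P_ij
  pi <- Re(eigen(t(P))$vectors[, 1]); pi <- pi / sum(pi)
  h <- -sum(pi * rowSums(P * log(P)))
  expect_equal(es$ST, h, tolerance = 0.02)
  expect_lt(abs(es$sTE), 0.005)
})

test_that("partial entropies are unrenormalized octant contributions", {
  a <- actions_from_indices(c(-1, 1))
  expect_equal(partial_entropy(pattern_counts(a, 2), "ad"), 0)

  # windows (-1,1) in run 1 and (1,-1) in run 2
  a2 <- actions_from_indices(c(-1, 1, 1, -1), run = c(1, 1, 2, 2))
  d2 <- pattern_counts(a2, 2)
  expect_equal(d2$p, c(0.5, 0.5))
  expect_equal(partial_entropy(d2, "ad"), 0.5 * log(2), tolerance = 1e-12)
  expect_equal(partial_entropy(d2, "da"), 0.5 * log(2), tolerance = 1e-12)

  expect_error(partial_entropy(d2, "ada"), class = "hrvdyn_validation_error")

  # the eight sign octants plus zero-containing terms partition E3
  set.seed(7)
  for (rep in 1:5) {
    a <- random_actions(300, M = 2)
    d3 <- pattern_counts(a, 3)
    octs <- c("aaa", "aad", "ada", "add", "daa", "dad", "dda", "ddd")
    part_sum <- sum(vapply(octs, function(p) partial_entropy(d3, p), 0))
    zero_mask <- d3$i1 == 0 | d3$i2 == 0 | d3$i3 == 0
    zero_term <- -sum(d3$p[zero_mask] * log(d3$p[zero_mask]))
    expect_equal(part_sum + zero_term, shannon_entropy(d3), tolerance = 1e-12)
  }
})

test_that("fragmentation indices match their defining patterns", {
  alt <- actions_from_indices(c(1, -1, 1, -1, 1))
  fr <- fragmentation(pattern_counts(alt, 2), pattern_counts(alt, 3), alt)
  expect_equal(fr$PIP, 100)
  expect_equal(fr$PAS, 100)
  expect_equal(fr$PSS, 100)

  mono <- actions_from_indices(rep(1, 4))
  fm <- fragmentation(pattern_counts(mono, 2), pattern_counts(mono, 3), mono)
  expect_equal(fm$PIP, 0)
  expect_equal(fm$PAS, 0)
  expect_equal(fm$p_ddd, 1)
  expect_equal(fm$PSS, 0)

  z <- actions_from_indices(c(0, 0, 1))
  fz <- fragmentation(pattern_counts(z, 2), pattern_counts(z, 3), z)
  expect_equal(fz$nzero, 2 / 3)
})

test_that("fragmentation and entropies match the naive oracle on random series", {
  set.seed(99)
  for (rep in 1:15) {
    a <- random_actions(sample(30:200, 1), M = sample(1:4, 1),
                        n_runs = sample(1:3, 1))
    tab2 <- naive_pattern_table(a, 2)
    tab3 <- naive_pattern_table(a, 3)
    if (length(tab2) == 0 || length(tab3) == 0) next
    d2 <- pattern_counts(a, 2); d3 <- pattern_counts(a, 3)
    k2 <- dist_as_keys(d2)
    expect_setequal(names(k2), names(tab2))
    expect_equal(as.numeric(k2[names(tab2)]), as.numeric(tab2))
    fr <- fragmentation(d2, d3, a)
    expect_equal(fr$p_ad, naive_octant_mass(tab2, "ad"), tolerance = 1e-12)
    expect_equal(fr$p_da, naive_octant_mass(tab2, "da"), tolerance = 1e-12)
    expect_equal(fr$p_ada, naive_octant_mass(tab3, "ada"), tolerance = 1e-12)
    expect_equal(fr$p_ddd, naive_octant_mass(tab3, "ddd"), tolerance = 1e-12)
    expect_equal(fr$PSS + (fr$p_aaa + fr$p_ddd) * 100, 100, tolerance = 1e-12)
    expect_equal(partial_entropy(d3, "dad"), naive_partial(tab3, "dad"),
                 tolerance = 1e-12)
  }
})
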