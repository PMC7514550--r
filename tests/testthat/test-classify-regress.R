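cluster_cohort <- function(n_per = 15, sep = 6, decades = c(20, 80), seed = 1) {
  set.seed(seed)
  k <- length(decades)
  feats <- tibble::tibble(
    meanRR = stats::rnorm(n_per * k) + rep(sep * seq_len(k), each = n_per),
    stdRR = stats::rnorm(n_per * k) + rep(sep * seq_len(k), each = n_per),
    age_years = rep(decades + 5L, each = n_per))
  build_cohort_matrix(feats, normalize = TRUE)
}

test_that("well-separated clusters are classified perfectly with calibrated posteriors", {
  cm <- cluster_cohort()
  res <- svm_classify(cm, kernel = "rbf", runs = 5, seed = 3)
  expect_gt(res$score_mean, 0.99)
  expect_equal(unname(rowSums(res$prob_mean)), rep(1, res$n), tolerance = 1e-9)
  pred <- colnames(res$prob_mean)[apply(res$prob_mean, 1, which.max)]
  expect_equal(pred, as.character(res$truth))
  expect_equal(glance(res)$score_mean, res$score_mean)
  expect_equal(nrow(tidy(res)), res$n * 2)
})

test_that("multi-run aggregates are deterministic given the master seed", {
  cm <- cluster_cohort(sep = 1.5)
  r1 <- svm_classify(cm, runs = 4, seed = 11)
  r2 <- svm_classify(cm, runs = 4, seed = 11)
  expect_identical(r1$prob_mean, r2$prob_mean)
  expect_identical(r1$scores, r2$scores)
})

test_that("decade subsets restrict rows to the named classes", {
  set.seed(3)
  ages <- rep(seq(20, 80, 10), c(30, 21, 33, 31, 27, 22, 17)) + 4L
  feats <- tibble::tibble(meanRR = stats::rnorm(181), stdRR = stats::rnorm(181),
                          age_years = ages)
  cm <- build_cohort_matrix(feats, normalize = TRUE)
  res <- svm_classify(cm, classes = c(20, 40, 60, 80), runs = 2, seed = 1)
  expect_equal(res$n, 107)
  expect_error(svm_classify(cm, classes = c(20, 90), runs = 1),
               class = "hrvdyn_validation_error")
  expect_error(svm_classify(cm, classes = c(20, 90), runs = 1), "90")
})

test_that("resubstitution scores bound k-fold scores and chance rules shuffled labels", {
  scores <- vapply(1:4, function(sd) {
    cm <- cluster_cohort(n_per = 20, sep = 1.2, seed = sd)
    c(svm_classify(cm, runs = 2, seed = sd)$score_mean,
      svm_classify(cm, runs = 2, seed = sd, evaluation = "kfold")$score_mean)
  }, c(resub = 0, kfold = 0))
  expect_gte(mean(scores["resub", ]), mean(scores["kfold", ]))

  # pure-noise features, k-fold: score compatible with chance = 1/2
  ch <- vapply(1:5, function(sd) {
    cm <- cluster_cohort(n_per = 20, sep = 0, seed = 100 + sd)
    svm_classify(cm, runs = 2, seed = sd, evaluation = "kfold")$score_mean
  }, 0)
  expect_lt(abs(mean(ch) - 0.5), 3 * stats::sd(ch) + 0.05)
})

test_that("age regression recovers exact lines and flags degeneracies", {
  set.seed(8)
  ages <- sample(20:89, 120, replace = TRUE)
  feats <- tibble::tibble(
    meanRR = 2 - 0.01 * ages,               # noiseless line
    stdRR = rep(7, 120),                    # constant
    RMSSD = stats::rnorm(120),              # pure noise
    age_years = ages)
  rep_ <- age_regression(build_cohort_matrix(feats))
  line <- rep_[rep_$feature == "meanRR", ]
  expect_equal(line$a1, -0.01, tolerance = 1e-12)
  expect_equal(line$a0, 2, tolerance = 1e-10)
  expect_equal(line$r_squared, 1, tolerance = 1e-9)
  cst <- rep_[rep_$feature == "stdRR", ]
  expect_true(cst$degenerate)
  expect_equal(cst$a1, 0)
  expect_equal(cst$r_squared, 0)
})

test_that("a pure-noise feature rarely shows a significant age slope", {
  hits <- vapply(1:50, function(sd) {
    set.seed(2000 + sd)
    ages <- rep(seq(20, 80, 10), c(30, 21, 33, 31, 27, 22, 17)) + 4L
    feats <- tibble::tibble(meanRR = stats::rnorm(181), age_years = ages)
    r <- age_regression(build_cohort_matrix(feats))
    r$p_a1 >= 0.05
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("distribution screens steer the group test and pairwise reporting", {
  set.seed(12)
  ages <- rep(c(24, 44, 64, 84), each = 30)
  # normal, equal-variance, strong group separation -> ANOVA path
  f_norm <- stats::rnorm(120, rep(c(0, 1, 2, 3), each = 30), 1)
  # heavy-tailed -> Kruskal-Wallis path
  f_skew <- exp(stats::rnorm(120, rep(c(0, 0.5, 1, 1.5), each = 30), 1))
  feats <- tibble::tibble(meanRR = f_norm, stdRR = f_skew, age_years = ages)
  r <- age_regression(build_cohort_matrix(feats))
  expect_equal(r$group_test[r$feature == "meanRR"], "anova")
  expect_equal(r$group_test[r$feature == "stdRR"], "kruskal")
  expect_true(grepl("20vs80", r$sig_pairs[r$feature == "meanRR"]))
})

test_that("Dunn's pairwise test matches a hand-computed example", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("A", "B", "C"), each = 3)
  d <- dunn_pairwise(v, g, adjust = "none")
  # mean ranks 2, 5, 8; se = sqrt((9*10/12)*(2/3)) = sqrt(5)
  expect_equal(d$z[d$g1 == "A" & d$g2 == "B"], -3 / sqrt(5), tolerance = 1e-12)
  expect_equal(d$p[d$g1 == "A" & d$g2 == "C"],
               2 * stats::pnorm(-6 / sqrt(5)), tolerance = 1e-12)
})

test_that("parameter recovery: generated age trends land inside the regression CI", {
  ok <- vapply(1:5, function(sd) {
    co <- generate_cohort(seed = 300 + sd)
    feats <- dplyr::bind_rows(lapply(co$series, time_domain))
    feats$age_years <- co$age_years
    fit <- stats::lm(meanRR ~ age_years, data = feats)
    ci <- stats::confint(fit)["age_years", ]
    ci[1] <= -0.850 && -0.850 <= ci[2]
  }, NA)
  expect_gte(mean(ok), 0.8)
})
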