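test_that("extract_features returns the 33 measures in canonical order", {
  s <- generate_subject(30, generator_params(duration_min = 60), seed = 5)
  f <- extract_features(s, oversample = 2)
  expect_equal(names(f)[1:33], hrv_feature_names())
  expect_true(all(is.finite(unlist(f[1, 1:33]))))
  expect_true(is.na(f$flags))
  # determinism: identical input -> bit-identical vector
  expect_identical(extract_features(s, oversample = 2)[, 1:33], f[, 1:33])
})

test_that("degenerate constant series yields the expected flagged/zero pattern", {
  s <- make_series(rep(800, 400))
  f <- extract_features(s)
  expect_equal(f$stdRR, 0)
  expect_equal(f$E1, 0)
  expect_equal(f$PIP, 0)
  expect_equal(f$nzero, 1)
  # a 2-beat series cannot support Poincare or spectra: flagged, not dropped
  f2 <- extract_features(make_series(c(800, 808)))
  expect_true(grepl("sd1", f2$flags))
  expect_true(is.na(f2$sd1))
  expect_false(is.na(f2$meanRR))
})

test_that("surrogate features differ only in dynamics-sensitive measures", {
  s <- generate_subject(45, generator_params(duration_min = 20, gap_rate = 0),
                        seed = 8)
  f <- extract_features(s, oversample = 2)
  fs <- extract_features(shuffle_surrogate(s, seed = 2), surrogate = 1,
                         oversample = 2)
  for (col in c("meanRR", "meanHR", "stdRR")) {
    expect_identical(f[[col]], fs[[col]])
  }
  for (col in c("RMSSD", "sd1", "ST", "sTE", "PIP")) {
    expect_false(f[[col]] == fs[[col]])
  }
})

test_that("segment features partition the recording consistently", {
  s <- generate_subject(40, generator_params(duration_min = 30, gap_rate = 0),
                        seed = 3)
  sf <- segment_features(s, length_min = 5, oversample = 2)
  expect_equal(nrow(sf), 6)
  expect_equal(sf$segment, 0:5)
  # beat-weighted mean of segment means reproduces the whole-window meanRR
  segs <- segment_rr(s, 5)
  w <- vapply(segs, nrow, 0L)
  expect_equal(sum(sf$meanRR * w) / sum(w), time_domain(s)$meanRR,
               tolerance = 0.005)
  sf10 <- segment_features(generate_subject(40, generator_params(duration_min = 10,
                                                                 gap_rate = 0),
                                            seed = 3),
                           length_min = 5, oversample = 2)
  expect_equal(nrow(sf10), 2)
})

test_that("extreme-segment selection minimizes its criterion with earliest-tie rule", {
  fake <- tibble::tibble(meanHR = c(60, 55, 58, 52, 57), stdRR = c(5, 4, 3, 4, 5),
                         segment = 0:4)
  expect_equal(select_extreme_segment(fake, "min_meanHR")$segment, 3)
  expect_equal(select_extreme_segment(fake, "min_stdRR")$segment, 2)
  ties <- tibble::tibble(meanHR = rep(60, 4), stdRR = rep(1, 4), segment = 0:3)
  expect_equal(select_extreme_segment(ties, "min_meanHR")$segment, 0)
  allna <- tibble::tibble(meanHR = rep(NA_real_, 3), stdRR = NA_real_,
                          segment = 0:2)
  expect_error(select_extreme_segment(allna, "min_meanHR"),
               class = "hrvdyn_validation_error")

  # a programmed low-variability epoch is found by min_stdRR
  set.seed(10)
  rr <- c(round(stats::rnorm(300, 900, 50)),   # ~4.5 min noisy
          round(stats::rnorm(350, 900, 3)),    # ~5.3 min quiet
          round(stats::rnorm(300, 900, 50)))
  sf <- segment_features(make_series(rr), length_min = 5, oversample = 2)
  pick <- select_extreme_segment(sf, "min_stdRR")
  expect_equal(pick$segment, 1)
})

test_that("cohort matrices carry decades, z-scoring and the stroboscopic shape", {
  set.seed(21)
  co <- generate_cohort(seed = 2)
  expect_equal(nrow(co), 181)
  # synthetic feature table standing in for full extraction
  feats <- tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(stats::rnorm(181 * 33), 181)), hrv_feature_names()))
  feats$age_years <- co$age_years
  cm <- build_cohort_matrix(feats, normalize = TRUE)
  expect_equal(dim(cm[, hrv_feature_names()]), c(181L, 33L))
  expect_true(all(cm$decade %in% seq(20, 80, 10)))
  expect_equal(unname(colMeans(as.matrix(cm[, hrv_feature_names()]))),
               rep(0, 33), tolerance = 1e-9)
  expect_equal(unname(apply(as.matrix(cm[, hrv_feature_names()]), 2, stats::sd)),
               rep(1, 33), tolerance = 1e-9)

  # surrogates are rescaled with the original cohort's statistics
  sur <- feats
  sur[hrv_feature_names()] <- sur[hrv_feature_names()] + 1
  surc <- apply_scaling(build_cohort_matrix(sur), attr(cm, "scaling"))
  expect_equal(mean(surc$meanRR),
               unname(1 / attr(cm, "scaling")$sd[1] + mean(cm$meanRR)),
               tolerance = 1e-8)

  # 5-min stroboscopic build: 48 x 181 rows
  strobo <- dplyr::bind_rows(lapply(0:47, function(k) {
    f <- feats; f$segment <- k; f
  }))
  expect_equal(nrow(build_cohort_matrix(strobo)), 8688)

  expect_warning(build_cohort_matrix(tibble::tibble(meanRR = stats::rnorm(3),
                                                    age_years = c(18, 30, 40))),
                 "18-19")
})

test_that("feature provenance round-trips through CSV", {
  s <- generate_subject(30, generator_params(duration_min = 10, gap_rate = 0),
                        seed = 4)
  f <- extract_features(s, window = "full", oversample = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(f, path)
  f2 <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(f2[, 1:33]), as.data.frame(f[, 1:33]),
               tolerance = 1e-12)
  expect_equal(f2$subject_id, f$subject_id)
  expect_equal(f2$window, f$window)
})
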