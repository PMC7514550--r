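#' SVM age-decade classification with posterior probabilities
#'
#' Multi-class support-vector classification of cohort rows into age
#' decades, via libsvm's one-vs-one scheme with pairwise-coupled Platt
#' posterior probabilities. The classifier is run `runs` times with per-run
#' seeds derived from `seed` (run-to-run variation enters through the
#' probability calibration's internal resampling); reported probabilities
#' and the score (fraction of rows whose argmax class equals their decade)
#' are the mean and sd over runs. Resubstitution evaluation reproduces
#' whole-cohort posterior tables; k-fold cross-validation is the sound
#' generalisation estimate and is recommended for any claim about unseen
#' subjects.
#'
#' @param cohort a z-scored `hrv_cohort`.
#' @param kernel `"rbf"` (Gaussian) or `"linear"`.
#' @param gamma Gaussian kernel width (default 0.2).
#' @param cost regularisation parameter C (default 1).
#' @param runs number of classifier runs (default 50).
#' @param classes decades to include (default: all present). A requested
#'   class with no members is an error naming it.
#' @param evaluation `"resubstitution"` or `"kfold"`.
#' @param folds number of folds for `evaluation = "kfold"`.
#' @param features feature subset to use (default all canonical features
#'   present; see [hrv_best10_features()]).
#' @param seed master seed; fixed seed gives an identical multi-run
#'   aggregate.
#' @return an object of class `hrv_svm` with `prob_mean`, `prob_sd`
#'   (subjects x classes), `scores` (per run), `score_mean`, `score_sd`,
#'   `truth`, and the settings.
#' @export
svm_classify <- function(cohort, kernel = c("rbf", "linear"), gamma = 0.2,
                         cost = 1, runs = 50, classes = NULL,
                         evaluation = c("resubstitution", "kfold"),
                         folds = 5, features = NULL, seed = 1) {
  kernel <- match.arg(kernel)
  evaluation <- match.arg(evaluation)
  if (!isTRUE(attr(cohort, "normalized"))) {
    rlang::warn("cohort is not z-scored; SVM kernels are scale-sensitive")
  }
  if (is.null(classes)) classes <- sort(unique(cohort$decade))
  absent <- setdiff(classes, cohort$decade)
  if (length(absent)) {
    rlang::abort(paste0("requested class(es) absent from cohort: ",
                        paste(absent, collapse = ", ")),
                 class = "hrvdyn_validation_error")
  }
  rows <- cohort$decade %in% classes
  features <- features %||% cohort_feature_cols(cohort)
  x <- as.matrix(cohort[rows, features])
  y <- factor(cohort$decade[rows], levels = sort(classes))
  ok <- stats::complete.cases(x)
  if (!all(ok)) {
    rlang::warn(sprintf("dropping %d row(s) with missing features", sum(!ok)))
    x <- x[ok, , drop = FALSE]; y <- y[ok]
  }
  if (any(table(y) < 2)) {
    rlang::abort("every requested class needs at least 2 members",
                 class = "hrvdyn_validation_error")
  }
  n <- nrow(x); k <- length(classes)
  svm_kernel <- if (kernel == "rbf") "radial" else "linear"
  probs <- array(NA_real_, c(n, k, runs),
                 dimnames = list(NULL, as.character(sort(classes)), NULL))
  scores <- numeric(runs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  for (r in seq_len(runs)) {
    set.seed(seed + r - 1L)
    if (evaluation == "resubstitution") {
      perm <- sample.int(n)
      fit <- e1071::svm(x[perm, , drop = FALSE], y[perm], kernel = svm_kernel,
                        gamma = gamma, cost = cost, probability = TRUE,
                        scale = FALSE)
      pr <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
      probs[, , r] <- pr[, dimnames(probs)[[2]], drop = FALSE]
    } else {
      fold <- sample(rep_len(seq_len(folds), n))
      for (fo in seq_len(folds)) {
        tr <- fold != fo
        fit <- e1071::svm(x[tr, , drop = FALSE], droplevels(y[tr]),
                          kernel = svm_kernel, gamma = gamma, cost = cost,
                          probability = TRUE, scale = FALSE)
        pr <- attr(stats::predict(fit, x[!tr, , drop = FALSE],
                                  probability = TRUE), "probabilities")
        probs[!tr, colnames(pr), r] <- pr
      }
      probs[, , r][is.na(probs[, , r])] <- 0
    }
    pred <- dimnames(probs)[[2]][apply(probs[, , r, drop = FALSE], 1, which.max)]
    scores[r] <- mean(pred == as.character(y))
  }
  structure(list(
    prob_mean = apply(probs, 1:2, mean), prob_sd = apply(probs, 1:2, stats::sd),
    scores = scores, score_mean = mean(scores), score_sd = stats::sd(scores),
    truth = y, classes = sort(classes), kernel = kernel, gamma = gamma,
    cost = cost, runs = runs, evaluation = evaluation,
    features = features, n = n, seed = seed),
    class = "hrv_svm")
}

#' @export
print.hrv_svm <- function(x, ...) {
  cat(sprintf("<hrv_svm> %s kernel, %s evaluation, %d rows x %d classes\n",
              x$kernel, x$evaluation, x$n, length(x$classes)))
  cat(sprintf("  score = %.1f +/- %.1f %% over %d runs\n",
              100 * x$score_mean, 100 * x$score_sd, x$runs))
  invisible(x)
}

#' Greedy forward feature selection by classification score
#'
#' Adds at each step the feature that most improves the mean SVM score,
#' reproducing the kind of search behind compact presets such as
#' [hrv_best10_features()]. Intended as an exploratory tool; scores are
#' evaluated with few runs for speed.
#'
#' @param cohort a z-scored `hrv_cohort`.
#' @param candidates candidate feature names.
#' @param max_features number of features to select.
#' @param runs classifier runs per evaluation.
#' @param ... passed to [svm_classify()].
#' @return tibble `step`, `feature`, `score` in selection order.
#' @export
select_features_greedy <- function(cohort, candidates = NULL, max_features = 10,
                                   runs = 3, ...) {
  candidates <- candidates %||% cohort_feature_cols(cohort)
  chosen <- character(); log <- list()
  for (step in seq_len(min(max_features, length(candidates)))) {
    rest <- setdiff(candidates, chosen)
    sc <- vapply(rest, function(f) {
      svm_classify(cohort, features = c(chosen, f), runs = runs, ...)$score_mean
    }, 0)
    best <- rest[which.max(sc)]
    chosen <- c(chosen, best)
    log[[step]] <- tibble::tibble(step = step, feature = best, score = max(sc))
  }
  dplyr::bind_rows(log)
}
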