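#' Pearson correlation matrix of cohort features
#'
#' @param cohort an `hrv_cohort` (or any tibble with feature columns).
#' @param use passed to [stats::cor()]'s `use` argument.
#' @return symmetric feature-by-feature correlation matrix; zero-variance
#'   features get correlation 0 off-diagonal with a warning naming them.
#' @export
correlation_matrix <- function(cohort, use = "pairwise.complete.obs") {
  cols <- cohort_feature_cols(cohort)
  if (nrow(cohort) < 3) {
    rlang::abort("need at least 3 rows", class = "hrvdyn_length_error")
  }
  x <- as.matrix(cohort[, cols])
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  flat <- names(sds)[!is.na(sds) & sds == 0]
  if (length(flat)) {
    rlang::warn(paste0("zero-variance feature(s), correlations set to 0: ",
                       paste(flat, collapse = ", ")))
  }
  m <- suppressWarnings(stats::cor(x, use = use))
  m[is.na(m)] <- 0
  diag(m) <- 1
  m
}

#' Graph of strong correlations
#'
#' Features are nodes; an undirected edge joins two features whose absolute
#' Pearson correlation meets the threshold. No self-loops.
#'
#' @param matrix a [correlation_matrix()].
#' @param theta absolute-correlation cutoff (default 0.8).
#' @return an object of class `hrv_corr_graph`: list with `edges` (tibble
#'   `from`, `to`, `r`), `graph` (igraph), `components` (membership named by
#'   feature) and `theta`.
#' @export
strong_correlation_graph <- function(matrix, theta = 0.8) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  nm <- rownames(matrix)
  ut <- which(upper.tri(matrix) & abs(matrix) >= theta, arr.ind = TRUE)
  edges <- tibble::tibble(from = nm[ut[, 1]], to = nm[ut[, 2]],
                          r = matrix[ut])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = tibble::tibble(name = nm))
  structure(list(edges = edges, graph = g,
                 components = igraph::components(g)$membership,
                 theta = theta),
            class = "hrv_corr_graph")
}

#' @export
print.hrv_corr_graph <- function(x, ...) {
  cat(sprintf("<hrv_corr_graph> theta=%.2f, %d nodes, %d edges, %d components\n",
              x$theta, igraph::vcount(x$graph), nrow(x$edges),
              max(x$components)))
  invisible(x)
}

#' Exploratory factor analysis of an HRV cohort
#'
#' Principal-component extraction: the factors are the eigenvectors of the
#' feature correlation matrix, loadings are eigenvectors scaled by the
#' square root of their eigenvalues, and factors are retained while their
#' eigenvalue strictly exceeds 1 (Kaiser-Guttman rule). Percent variance per
#' factor is eigenvalue / number of features x 100. Each feature's dominant
#' factor is the retained factor with the largest absolute loading. No
#' rotation is applied by default; varimax is available.
#'
#' @param cohort a z-scored `hrv_cohort` (a warning is emitted otherwise).
#' @param rotation `"none"` or `"varimax"`.
#' @param min_row_ratio warn when rows < `min_row_ratio` x retained factors.
#' @return an object of class `hrv_fa`: loadings (features x retained
#'   factors), `eigenvalues` (all), `pct_var`, `dominant` tibble, `rotation`
#'   and the feature names used.
#' @export
factor_analysis <- function(cohort, rotation = c("none", "varimax"),
                            min_row_ratio = 5) {
  rotation <- match.arg(rotation)
  if (!isTRUE(attr(cohort, "normalized"))) {
    rlang::warn("cohort is not z-scored; factoring the correlation matrix anyway")
  }
  m <- correlation_matrix(cohort)
  ev <- eigen(m, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    rlang::abort("correlation matrix is not positive semidefinite",
                 class = "hrvdyn_validation_error")
  }
  vals <- pmax(ev$values, 0)
  keep <- which(vals > 1 + 1e-9)   # strictly greater, guarded against rounding
  p <- ncol(m)
  if (length(keep) && nrow(cohort) < min_row_ratio * length(keep)) {
    rlang::warn(sprintf("only %d rows for %d retained factors", nrow(cohort),
                        length(keep)))
  }
  load <- if (length(keep)) {
    L <- ev$vectors[, keep, drop = FALSE] %*% diag(sqrt(vals[keep]), length(keep))
    dimnames(L) <- list(rownames(m), paste0("F", seq_along(keep)))
    if (rotation == "varimax" && length(keep) > 1) {
      L <- stats::varimax(L)$loadings
      L <- matrix(as.numeric(L), nrow(m), length(keep),
                  dimnames = list(rownames(m), paste0("F", seq_along(keep))))
    }
    L
  } else {
    matrix(numeric(), p, 0, dimnames = list(rownames(m), NULL))
  }
  dominant <- if (ncol(load)) {
    tibble::tibble(
      feature = rownames(load),
      factor = colnames(load)[apply(abs(load), 1, which.max)],
      loading = load[cbind(seq_len(p), apply(abs(load), 1, which.max))])
  } else tibble::tibble(feature = rownames(m), factor = NA_character_,
                        loading = NA_real_)
  structure(list(loadings = load, eigenvalues = vals,
                 pct_var = vals[keep] / p * 100, dominant = dominant,
                 rotation = rotation, features = rownames(m),
                 n_retained = length(keep)),
            class = "hrv_fa")
}

#' @export
print.hrv_fa <- function(x, ...) {
  cat(sprintf("<hrv_fa> %d features, %d retained factor(s) [eigenvalue > 1], rotation=%s\n",
              length(x$features), x$n_retained, x$rotation))
  if (x$n_retained) {
    cat("  % variance:", paste(sprintf("%.1f", x$pct_var), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reconstruction error of a truncated factor model
#'
#' Frobenius norm of the difference between the correlation matrix and its
#' rank-`k` loading reconstruction; non-increasing in `k`.
#'
#' @param corr correlation matrix.
#' @param k number of leading factors used.
#' @return the Frobenius error.
#' @export
fa_reconstruction_error <- function(corr, k) {
  ev <- eigen(corr, symmetric = TRUE)
  L <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[seq_len(k)], 0)), k)
  sqrt(sum((corr - L %*% t(L))^2))
}
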