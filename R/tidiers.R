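#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a factor model
#'
#' @param x an `hrv_fa` object.
#' @param ... unused.
#' @return long tibble `feature`, `factor`, `loading`, `dominant`.
#' @method tidy hrv_fa
#' @export
tidy.hrv_fa <- function(x, ...) {
  if (x$n_retained == 0) {
    return(tibble::tibble(feature = character(), factor = character(),
                          loading = numeric(), dominant = logical()))
  }
  out <- tibble::as_tibble(x$loadings, rownames = "feature")
  out <- tidyr::pivot_longer(out, -"feature", names_to = "factor",
                             values_to = "loading")
  dom <- stats::setNames(x$dominant$factor, x$dominant$feature)
  out$dominant <- out$factor == dom[out$feature]
  out
}

#' @rdname tidy.hrv_fa
#' @method glance hrv_fa
#' @export
glance.hrv_fa <- function(x, ...) {
  tibble::tibble(n_features = length(x$features),
                 n_factors = x$n_retained,
                 pct_var_total = sum(x$pct_var),
                 rotation = x$rotation)
}

#' Tidy an SVM classification result
#'
#' @param x an `hrv_svm` object.
#' @param ... unused.
#' @return long tibble `subject`, `truth`, `class`, `prob_mean`, `prob_sd`.
#' @method tidy hrv_svm
#' @export
tidy.hrv_svm <- function(x, ...) {
  k <- length(x$classes)
  tibble::tibble(
    subject = rep(seq_len(x$n), k),
    truth = rep(as.integer(as.character(x$truth)), k),
    class = rep(as.integer(colnames(x$prob_mean)), each = x$n),
    prob_mean = as.vector(x$prob_mean),
    prob_sd = as.vector(x$prob_sd))
}

#' @rdname tidy.hrv_svm
#' @method glance hrv_svm
#' @export
glance.hrv_svm <- function(x, ...) {
  tibble::tibble(score_mean = x$score_mean, score_sd = x$score_sd,
                 runs = x$runs, kernel = x$kernel, gamma = x$gamma,
                 cost = x$cost, evaluation = x$evaluation,
                 n = x$n, n_classes = length(x$classes))
}

#' Edge list of a strong-correlation graph
#'
#' @param x an `hrv_corr_graph`.
#' @param ... unused.
#' @return tibble `from`, `to`, `r`.
#' @method tidy hrv_corr_graph
#' @export
tidy.hrv_corr_graph <- function(x, ...) x$edges

#' @rdname tidy.hrv_corr_graph
#' @method glance hrv_corr_graph
#' @export
glance.hrv_corr_graph <- function(x, ...) {
  tibble::tibble(theta = x$theta, n_nodes = igraph::vcount(x$graph),
                 n_edges = nrow(x$edges),
                 n_components = max(x$components))
}
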