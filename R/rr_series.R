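#' Construct an RR-interval series
#'
#' An `rr_series` is a tibble with one row per normal beat and columns
#' `rr_ms` (the RR interval ending at that beat, in ms), `t_s` (cumulative
#' beat time in seconds) and `gap_before` (integer number of missing beats
#' between this beat and the previous one; 0 means contiguous). Subject
#' metadata and the recorder quantum live in attributes so the object pipes
#' through dplyr verbs like any tibble.
#'
#' @param rr_ms numeric vector of RR intervals in milliseconds.
#' @param gap_before integer vector (recycled) of missing-beat counts before
#'   each beat; the first beat always gets 0.
#' @param t_s optional numeric vector of beat times in seconds. If omitted,
#'   times are the cumulative sum of `rr_ms / 1000`.
#' @param subject_id,age_years subject metadata.
#' @param delta recorder quantum in ms. If `NULL` it is inferred with
#'   [infer_delta()].
#' @param meta free-form provenance list.
#' @return A tibble of class `rr_series`.
#' @examples
#' rr_series(c(800, 808, 816))
#' @export
rr_series <- function(rr_ms, gap_before = 0L, t_s = NULL,
                      subject_id = NA_character_, age_years = NA_integer_,
                      delta = NULL, meta = list()) {
  rr_ms <- as.numeric(rr_ms)
  if (any(!is.finite(rr_ms)) || any(rr_ms <= 0)) {
    rlang::abort("all RR intervals must be finite and positive",
                 class = "hrvdyn_validation_error")
  }
  n <- length(rr_ms)
  gap_before <- as.integer(rep_len(gap_before, n))
  if (n > 0) gap_before[1] <- 0L
  if (is.null(t_s)) t_s <- cumsum(rr_ms) / 1000
  if (is.null(delta)) delta <- infer_delta(rr_ms)
  out <- tibble::tibble(rr_ms = rr_ms, t_s = as.numeric(t_s),
                        gap_before = gap_before)
  new_rr_series(out, subject_id = subject_id,
                age_years = as.integer(age_years), delta = delta, meta = meta)
}

new_rr_series <- function(df, subject_id, age_years, delta, meta = list()) {
  structure(df,
            class = c("rr_series", class(tibble::tibble())),
            subject_id = subject_id, age_years = age_years,
            delta = delta, meta = meta)
}

#' Metadata accessors for RR series
#'
#' @param x an `rr_series`.
#' @return `rr_delta()` the recorder quantum (ms); `rr_subject()` the subject
#'   id; `rr_age()` the age in years; `rr_duration_min()` the recording span
#'   in minutes.
#' @export
rr_delta <- function(x) attr(x, "delta")

#' @rdname rr_delta
#' @export
rr_subject <- function(x) attr(x, "subject_id")

#' @rdname rr_delta
#' @export
rr_age <- function(x) attr(x, "age_years")

#' @rdname rr_delta
#' @export
rr_duration_min <- function(x) {
  if (nrow(x) == 0) return(0)
  (x$t_s[nrow(x)] - x$t_s[1] + x$rr_ms[1] / 1000) / 60
}

# carry rr_series attributes onto a rebuilt tibble
rr_rebuild <- function(df, template) {
  new_rr_series(tibble::as_tibble(df),
                subject_id = attr(template, "subject_id"),
                age_years = attr(template, "age_years"),
                delta = attr(template, "delta"),
                meta = attr(template, "meta"))
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> subject=%s age=%s beats=%d duration=%.1f min delta=%.4g ms\n",
              rr_subject(x), rr_age(x), nrow(x), rr_duration_min(x), rr_delta(x)))
  NextMethod()
}

#' Infer the recorder quantum of an RR series
#'
#' The quantum is the greatest common divisor (up to floating tolerance) of
#' the distinct interval values and their differences; an 8 ms Holter
#' resolution is recovered from intervals such as 800, 808, 816.
#'
#' @param rr_ms numeric vector of intervals in ms.
#' @param tol absolute tolerance for the real-valued Euclid reduction.
#' @return the quantum in ms (>= `tol`); 1 if it cannot be resolved.
#' @export
infer_delta <- function(rr_ms, tol = 1e-6) {
  v <- sort(unique(round(as.numeric(rr_ms), 9)))
  if (length(v) < 2) return(if (length(v) == 1) v else 1)
  g <- abs(diff(v))
  g <- g[g > tol]
  if (length(g) == 0) return(1)
  gcd2 <- function(a, b) {
    while (b > tol) {
      r <- a %% b
      if (r > b - tol) r <- 0           # guard float wrap-around
      a <- b; b <- r
    }
    a
  }
  out <- Reduce(gcd2, g)
  if (out <= tol) 1 else out
}

#' Read an RR-interval series from a delimited text file
#'
#' Three dialects are supported: a single `rr_ms` column, a two-column
#' `t_s` + `rr_ms` file, and an annotated CSV with an extra `gap` column
#' giving the number of missing beats before a row. Headerless files are
#' accepted for the one- and two-column dialects.
#'
#' @param path file path.
#' @param dialect one of `"auto"`, `"rr"`, `"time_rr"`, `"annotated"`.
#' @param delta recorder quantum in ms; inferred when `NULL`.
#' @param subject_id,age_years metadata attached to the result.
#' @return an [rr_series()].
#' @export
read_rr_series <- function(path, dialect = c("auto", "rr", "time_rr", "annotated"),
                           delta = NULL, subject_id = NA_character_,
                           age_years = NA_integer_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "hrvdyn_io_error")
  }
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- suppressWarnings(readr::read_csv(
    path, col_names = has_header,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE))
  if (!has_header) {
    names(df) <- switch(as.character(ncol(df)),
                        "1" = "rr_ms", "2" = c("t_s", "rr_ms"),
                        "3" = c("t_s", "rr_ms", "gap"),
                        rlang::abort("cannot guess columns of headerless file",
                                     class = "hrvdyn_io_error"))
  }
  if (dialect == "auto") {
    dialect <- if ("gap" %in% names(df)) "annotated"
               else if ("t_s" %in% names(df)) "time_rr" else "rr"
  }
  need <- switch(dialect, rr = "rr_ms", time_rr = c("t_s", "rr_ms"),
                 annotated = "rr_ms")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    rlang::abort(paste0("missing column(s): ", paste(miss, collapse = ", ")),
                 class = "hrvdyn_io_error")
  }
  parse_num <- function(col, what) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad)) {
      rlang::abort(sprintf("non-numeric %s at line %d: '%s'", what,
                           bad[1] + has_header, df[[col]][bad[1]]),
                   class = "hrvdyn_parse_error")
    }
    x
  }
  rr <- parse_num("rr_ms", "rr_ms")
  if (any(rr <= 0, na.rm = TRUE)) {
    rlang::abort("non-positive RR interval in file",
                 class = "hrvdyn_validation_error")
  }
  t_s <- if ("t_s" %in% names(df) && dialect != "rr") parse_num("t_s", "t_s") else NULL
  gap <- if ("gap" %in% names(df)) {
    g <- parse_num("gap", "gap flag")
    g[is.na(g)] <- 0
    as.integer(g)
  } else 0L
  rr_series(rr, gap_before = gap, t_s = t_s, subject_id = subject_id,
            age_years = age_years, delta = delta)
}

#' Write an RR-interval series as annotated CSV
#'
#' Writes `t_s`, `rr_ms`, `gap` columns; [read_rr_series()] on the result
#' round-trips intervals and gap flags exactly.
#'
#' @param series an `rr_series`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rr_series <- function(series, path) {
  out <- tibble::tibble(t_s = series$t_s, rr_ms = series$rr_ms,
                        gap = series$gap_before)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
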