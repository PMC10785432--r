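#' Naive total-count ratio normalization estimate
#'
#' The simplest comparator: the log2 ratio of (pseudocount-smoothed) total
#' reads over the invariant set, reference over query.
#'
#' @param counts_x Query sample counts (nonnegative integers).
#' @param counts_y Reference sample counts, same length.
#' @param pseudocount Added once to each total before the ratio is taken.
#' @return A `point_estimate` list: `method`, `log2_factor`,
#'   `slope` (= 2^log2_factor), `intercept` (0 for this method), `n_regions`.
#' @export
ratio_estimate <- function(counts_x, counts_y, pseudocount = 1) {
  check_count_pair(counts_x, counts_y, min_len = 1L)
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  # difference of logs, so swapping the samples negates the factor exactly
  lf <- log2(sum(counts_y) + pseudocount) - log2(sum(counts_x) + pseudocount)
  point_estimate("ratio", lf, intercept = 0, n = length(counts_x))
}

#' Ordinary least-squares normalization estimate
#'
#' Unweighted linear regression of reference counts on query counts; the
#' slope is the normalization factor. An optional variant regresses
#' log2-smoothed counts instead (off by default).
#'
#' @inheritParams ratio_estimate
#' @param log_scale If `TRUE`, fit on `log2(counts + pseudocount)` instead
#'   of the raw scale.
#' @param pseudocount Used only when `log_scale = TRUE`.
#' @return A `point_estimate` list (see [ratio_estimate()]).
#' @export
ols_estimate <- function(counts_x, counts_y, log_scale = FALSE, pseudocount = 1) {
  check_count_pair(counts_x, counts_y, min_len = 2L)
  if (log_scale) {
    fit <- stats::lm(log2(counts_y + pseudocount) ~ log2(counts_x + pseudocount))
    co <- unname(stats::coef(fit))
    # on the log scale the fitted slope is an elasticity, not a factor; the
    # factor is recovered from the fit at the mean query intensity
    lf <- unname(stats::predict(fit, newdata = data.frame(
      counts_x = mean(counts_x))) - log2(mean(counts_x) + pseudocount))
    return(point_estimate("ols", lf, intercept = co[1], n = length(counts_x)))
  }
  if (stats::var(counts_x) < .Machine$double.eps)
    stop("counts_x is constant: degenerate regression design")
  fit <- stats::lm(counts_y ~ counts_x)
  co <- unname(stats::coef(fit))
  slope <- co[2]
  if (slope <= 0)
    stop(sprintf("least-squares slope is non-positive (%.4g); log2 factor undefined", slope))
  point_estimate("ols", log2(slope), intercept = co[1], n = length(counts_x))
}

point_estimate <- function(method, log2_factor, intercept, n) {
  structure(list(method = method, log2_factor = log2_factor,
                 slope = 2^log2_factor, intercept = intercept,
                 n_regions = as.integer(n)),
            class = "point_estimate")
}

#' @export
print.point_estimate <- function(x, ...) {
  cat(sprintf("%s estimate: log2 factor %.4f (slope %.4f%s) over %d regions\n",
              x$method, x$log2_factor, x$slope,
              if (x$method == "ols") sprintf(", intercept %.4f", x$intercept) else "",
              x$n_regions))
  invisible(x)
}

#' @rdname ratio_estimate
#' @param x A `point_estimate`.
#' @param path Output JSON path.
#' @export
write_point_estimate <- function(x, path) {
  stopifnot(inherits(x, "point_estimate"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

check_count_pair <- function(x, y, min_len) {
  if (length(x) != length(y))
    stop("counts_x and counts_y must have the same length")
  if (length(x) < min_len)
    stop(sprintf("at least %d regions required", min_len))
  if (any(x < 0) || any(y < 0)) stop("counts must be nonnegative")
  invisible(TRUE)
}
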