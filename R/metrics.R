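#' Distinguishability of related and unrelated LCL distributions
#'
#' An empirical separation statistic for two samples of lower confidence
#' limits (LCLs) on \eqn{\ln LR}:
#' \deqn{D = \frac{(\bar x_R - \bar x_U)^2}{s^2_R + s^2_U},}
#' the squared mean difference over the summed unbiased sample variances —
#' analogous to the non-centrality parameter of the LR test statistic under
#' the alternative. `-Inf` entries (degenerate zero-LR pairs) are excluded
#' from the moments; at least two finite values per sample are required,
#' otherwise `NA` is returned (e.g. parent-offspring LRs on unrelated
#' pairs, which are almost always zero).
#'
#' @param related,unrelated Numeric vectors of LCL values (may contain
#'   `-Inf`).
#' @return A non-negative scalar, or `NA` when not estimable. Attributes
#'   `n_finite_related` and `n_finite_unrelated` carry the finite counts.
#' @examples
#' distinguishability(c(9, 10, 11), c(-1, 0, 1))
#' @export
distinguishability <- function(related, unrelated) {
  r <- related[is.finite(related)]
  u <- unrelated[is.finite(unrelated)]
  d <- if (length(r) < 2 || length(u) < 2) {
    NA_real_
  } else {
    (mean(r) - mean(u))^2 / (var(r) + var(u))
  }
  structure(d,
    n_finite_related = length(r),
    n_finite_unrelated = length(u)
  )
}

#' Empirical power and false-positive-rate curve over LCL thresholds
#'
#' For each decision threshold `t`, power is the fraction of related-pair
#' LCLs strictly above `t` and the false positive rate the fraction of
#' unrelated-pair LCLs strictly above `t` (ties count as non-detections;
#' `-Inf` LCLs fall below every threshold). Both curves are non-increasing
#' in `t`.
#'
#' @param related,unrelated Numeric vectors of LCL values.
#' @param thresholds Threshold grid; default `-Inf` followed by
#'   `n_thresholds` evenly spaced points spanning the pooled finite range.
#' @param n_thresholds Number of grid points when `thresholds` is `NULL`.
#' @return A tibble with columns `threshold`, `power`, `fpr`.
#' @export
power_fpr_curve <- function(related, unrelated, thresholds = NULL,
                            n_thresholds = 101) {
  if (is.null(thresholds)) {
    fin <- c(related[is.finite(related)], unrelated[is.finite(unrelated)])
    if (length(fin) == 0) {
      abort("no finite LCL values to span a threshold grid",
        class = "famlr_validation_error"
      )
    }
    thresholds <- c(-Inf, seq(min(fin), max(fin), length.out = n_thresholds))
  }
  if (length(thresholds) == 0) {
    abort("empty threshold grid", class = "famlr_config_error")
  }
  thresholds <- sort(thresholds)
  tibble::tibble(
    threshold = thresholds,
    power = vapply(thresholds, function(t) mean(related > t), 0),
    fpr = vapply(thresholds, function(t) mean(unrelated > t), 0)
  )
}

#' Pearson correlation with validation
#'
#' Standard Pearson product-moment correlation, used for panel-level
#' summaries such as distinguishability versus average gene diversity or
#' versus FST. Requires at least 3 paired values and non-degenerate
#' variances (otherwise `NA`).
#'
#' @param x,y Numeric vectors of equal length.
#' @return The correlation in `[-1, 1]`, or `NA` when not estimable.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3",
      class = "famlr_validation_error"
    )
  }
  if (var(x) == 0 || var(y) == 0) {
    return(NA_real_)
  }
  cor(x, y)
}
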