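# Bootstrap confidence intervals and rank-sum tests for aggregate
# conservation statistics.

#' Bootstrap confidence interval for a mean
#'
#' Resamples a fixed fraction of the values *without replacement* (default:
#' half the data, one thousand times), computes the mean of every resample,
#' and reports the percentile interval containing 95% of those means.
#'
#' @param values Numeric vector (length >= 4; NAs dropped).
#' @param n_resamples Number of resamples (default 1000).
#' @param fraction Fraction drawn per resample (default 0.5).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `bootstrap_result`: list with `estimate` (the
#'   full-sample mean), `ci_low`, `ci_high`, `n`, `n_resamples`, `fraction`,
#'   `seed`.
#' @export
bootstrap_mean_ci <- function(values, n_resamples = 1000, fraction = 0.5,
                              seed = 1, conf = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 4) stop("need at least 4 values")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  k <- max(1, floor(fraction * length(values)))
  means <- vapply(seq_len(n_resamples),
                  function(i) mean(values[sample.int(length(values), k)]),
                  numeric(1))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE)
  structure(list(estimate = mean(values), ci_low = ci[1], ci_high = ci[2],
                 n = length(values), n_resamples = n_resamples,
                 fraction = fraction, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("mean %.4f, 95%% bootstrap CI [%.4f, %.4f] (n=%d, %d resamples of %.0f%%)\n",
              x$estimate, x$ci_low, x$ci_high, x$n, x$n_resamples,
              100 * x$fraction))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Non-parametric comparison of two samples (Mann-Whitney); delegates to
#' `stats::wilcox.test`, which matches exact enumeration on small tie-free
#' samples.
#'
#' @param x,y Numeric vectors (non-empty).
#' @return List with `statistic` (W) and `p_value`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
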