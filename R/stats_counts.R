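# Percent-rank dispersion analysis of per-cell lipid-body counts. Count
# distributions are heavily tied and strongly non-normal (most cells show
# no LB in the focal plane), so location/dispersion is reported through
# empirical percentiles rather than standard deviations.

#' Percent-rank summary of per-cell counts
#'
#' Empirical percentile summary under the nearest-rank convention:
#' `percentile(p) = sorted[ceiling(p/100 * n)]` for p > 0 and the minimum
#' at p = 0. The median is `percentile(50)`; box ranges cover the 25-75 and
#' 5-95 percentile intervals.
#'
#' @param counts non-negative integer vector (n >= 1).
#' @return A `percent_rank_summary`: `sorted`, `percentile` (function),
#'   `median`, `mean`, `box_25_75`, `box_5_95`, `n`.
#' @export
percent_rank <- function(counts) {
  if (length(counts) == 0) stop("empty input")
  stopifnot(all(counts >= 0))
  s <- sort(counts)
  n <- length(s)
  pctl <- function(p) {
    stopifnot(all(p >= 0), all(p <= 100))
    ifelse(p == 0, s[1], s[pmax(1, ceiling(p / 100 * n))])
  }
  structure(list(sorted = s, percentile = pctl,
                 median = pctl(50), mean = mean(s),
                 box_25_75 = c(pctl(25), pctl(75)),
                 box_5_95 = c(pctl(5), pctl(95)), n = n),
            class = "percent_rank_summary")
}

#' @export
print.percent_rank_summary <- function(x, ...) {
  cat(sprintf("<percent_rank_summary> n = %d, median %g, mean %.3g, 25-75%% [%g, %g], 5-95%% [%g, %g]\n",
              x$n, x$median, x$mean, x$box_25_75[1], x$box_25_75[2],
              x$box_5_95[1], x$box_5_95[2]))
  invisible(x)
}

#' Integer histogram of per-cell counts
#'
#' Exact distribution of LB counts per cell, with empty bins reported as 0
#' up to the maximum observed count. The mass sums to n.
#'
#' @inheritParams percent_rank
#' @return data frame with `count` (0..max) and `cells`.
#' @export
count_histogram <- function(counts) {
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  mx <- if (length(counts)) max(counts) else 0
  data.frame(count = 0:mx,
             cells = as.integer(tabulate(counts + 1L, nbins = mx + 1L)))
}

#' Fraction of cells with zero lipid bodies
#' @inheritParams percent_rank
#' @export
zero_fraction <- function(counts) {
  stopifnot(all(counts >= 0))
  if (length(counts) == 0) return(NaN)
  mean(counts == 0)
}
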