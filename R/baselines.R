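#' Fisher score of a feature
#'
#' Classical multi-class Fisher criterion: weighted between-class scatter
#' over weighted within-class scatter,
#' \deqn{F = \frac{\sum_c n_c(\mu_c - \mu)^2}
#'               {\sum_c n_c \sigma_c^2 + \epsilon}}
#' with population (biased) class variances and a small
#' \eqn{\epsilon = 10^{-12}} guarding degenerate within-class variance.
#'
#' @param x Numeric feature vector.
#' @param labels Discrete labels, same length; at least 2 classes.
#' @return Non-negative scalar score.
#' @export
fisher_score <- function(x, labels) {
  labels <- factor(labels)
  if (length(labels) != length(x)) stop_data("labels length mismatch")
  if (nlevels(labels) < 2L) stop_data("need at least 2 classes")
  mu <- mean(x)
  between <- 0
  within <- 0
  for (cl in levels(labels)) {
    xc <- x[labels == cl]
    nc <- length(xc)
    mc <- mean(xc)
    between <- between + nc * (mc - mu)^2
    within <- within + nc * mean((xc - mc)^2)
  }
  between / (within + 1e-12)
}

#' Hellinger-distance score of a feature
#'
#' Distributional separation between classes: the feature is min-max
#' normalized, binned on `bins` equal-width bins over [0, 1], and the
#' Hellinger distance
#' \deqn{H(p, q) = \sqrt{1 - \sum_b \sqrt{p_b q_b}}}
#' between per-class relative-frequency histograms is averaged over all
#' unordered class pairs. Lies in [0, 1]; 0 for identical class
#' distributions (including any constant feature), 1 for disjoint support.
#'
#' @param x Numeric feature vector.
#' @param labels Discrete labels, same length; at least 2 classes.
#' @param bins Number of histogram bins (>= 2); default 10.
#' @return Scalar score in [0, 1].
#' @export
hellinger_score <- function(x, labels, bins = 10) {
  labels <- factor(labels)
  if (length(labels) != length(x)) stop_data("labels length mismatch")
  if (nlevels(labels) < 2L) stop_data("need at least 2 classes")
  if (!is.numeric(bins) || length(bins) != 1L || bins < 2)
    stop_data("`bins` must be an integer >= 2")
  z <- suppressWarnings(minmax_normalize(x))
  bin <- pmin(floor(z * bins) + 1L, as.integer(bins))
  hists <- vapply(levels(labels), function(cl) {
    b <- bin[labels == cl]
    tabulate(b, nbins = as.integer(bins)) / length(b)
  }, numeric(as.integer(bins)))
  pairs <- utils::combn(ncol(hists), 2L)
  h <- vapply(seq_len(ncol(pairs)), function(k) {
    p <- hists[, pairs[1L, k]]
    q <- hists[, pairs[2L, k]]
    bc <- sum(sqrt(p * q))
    sqrt(max(0, 1 - bc))
  }, numeric(1))
  mean(h)
}

#' Hellinger pairwise distance between two histograms
#'
#' Convenience wrapper used in tests and reports.
#'
#' @param p,q Relative-frequency histograms on the same bins.
#' @return Hellinger distance in [0, 1].
#' @export
hellinger_distance <- function(p, q) {
  if (length(p) != length(q)) stop_data("histogram length mismatch")
  sqrt(max(0, 1 - sum(sqrt(p * q))))
}
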