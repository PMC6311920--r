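#' Min-max normalization to [0, 1]
#'
#' Affine rescaling \eqn{(x - \min x)/(\max x - \min x)}. A constant vector
#' has no scale; it maps to all zeros with a warning.
#'
#' @param x Numeric vector.
#' @return Numeric vector in [0, 1].
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 1L) stop_data("`x` must be non-empty")
  if (any(!is.finite(x))) stop_data("`x` must be finite")
  rng <- range(x)
  if (rng[1L] == rng[2L]) {
    warning("constant vector: min-max normalization maps it to all zeros")
    return(rep(0, length(x)))
  }
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Kernel density estimates underlying the mutual-information weight
#'
#' Plug-in Gaussian-kernel estimates evaluated at the observed points, for a
#' continuous feature paired with discrete labels through the 0/1 label
#' metric \eqn{d(y_i, y_j)}:
#' \deqn{f(x_i) = \frac{1}{\sqrt{2\pi}\,n}\sum_j e^{-(x_i-x_j)^2/2}}
#' \deqn{f(y_i) = \frac{1}{\sqrt{2\pi}\,n}\sum_j e^{-d(y_i,y_j)/2}}
#' \deqn{f(x_i,y_i) = \frac{1}{2\pi n}\sum_k e^{-D_k(x_i,y_i)/2},\quad
#'       D_k = \sqrt{(x_i-x_k)^2 + d(y_k,y_i)}}
#' The joint kernel deliberately applies the exponential to the root of the
#' mixed squared distance (not to its square), while the marginals use
#' squared distances; see the package vignette for discussion.
#'
#' @param x Numeric vector already normalized to [0, 1] (see
#'   [minmax_normalize()]).
#' @param labels Factor/character vector of discrete labels, same length.
#' @param bandwidth Kernel bandwidth `h` applied to the feature axis as
#'   \eqn{(x_i - x_j)/h}; default 1 (the estimator's printed form).
#' @return A list with `f_x`, `f_y`, `f_xy` (length-n positive vectors)
#'   and `D` (the n x n mixed distance matrix).
#' @export
estimate_densities <- function(x, labels, bandwidth = 1) {
  n <- length(x)
  if (length(labels) != n)
    stop_data("labels length (", length(labels),
              ") does not match feature length (", n, ")")
  assert_scalar_number(bandwidth, "bandwidth", 0, Inf, open = TRUE)
  d <- label_distance_matrix(labels)
  dx <- outer(x, x, `-`) / bandwidth
  f_x <- rowSums(exp(-dx^2 / 2)) / (sqrt(2 * pi) * n)
  f_y <- rowSums(exp(-d / 2)) / (sqrt(2 * pi) * n)
  D <- sqrt(dx^2 + d)
  f_xy <- rowSums(exp(-D / 2)) / (2 * pi * n)
  list(f_x = f_x, f_y = f_y, f_xy = f_xy, D = D)
}

#' Mutual-information weight of one feature against discrete labels
#'
#' The plug-in estimator
#' \deqn{I(x, Y) = \frac{1}{n}\sum_i \log
#'       \frac{f(x_i, y_i)}{f(x_i)\,f(y_i)}}
#' with the kernel densities of [estimate_densities()], computed on the
#' min-max-normalized feature. A constant feature has weight exactly 0 (the
#' joint and product kernels cancel term by term because the 0/1 label
#' metric satisfies \eqn{\sqrt{d} = d}). Weights may be slightly negative:
#' the plug-in estimator is not constrained to be non-negative.
#'
#' @param x Numeric vector: the raw feature row (normalized internally).
#' @param labels Discrete labels, same length as `x`; at least 2 samples.
#' @param log_base Base of the logarithm; default `exp(1)` (nats).
#' @param bandwidth Kernel bandwidth; default 1.
#' @return A single finite numeric weight.
#' @export
mi_weight <- function(x, labels, log_base = exp(1), bandwidth = 1) {
  if (length(x) < 2L) stop_data("need at least 2 samples")
  z <- suppressWarnings(minmax_normalize(x))
  est <- estimate_densities(z, labels, bandwidth = bandwidth)
  mean(log(est$f_xy / (est$f_x * est$f_y))) / log(log_base)
}

#' Weight every feature of an expression matrix
#'
#' Applies the selected per-feature weighting to each row and attaches a
#' deterministic ranking: weights sorted in decreasing order, ties broken
#' by ascending row index.
#'
#' @param matrix An [expr_matrix()] (typically after
#'   [filter_low_expression()]).
#' @param labels Labels named by sample id, or a bare vector ordered like
#'   the matrix columns.
#' @param method `"mi"` (kernel-density mutual information), `"fisher"` or
#'   `"hellinger"`.
#' @param log_base,bandwidth Passed to [mi_weight()] (MI method only).
#' @param bins Passed to [hellinger_score()] (Hellinger method only).
#' @return A `weight_vector`: data.frame with columns `feature_id`,
#'   `weight`, `rank` in the original row order, with the method recorded
#'   as an attribute.
#' @export
weight_all <- function(matrix, labels, method = c("mi", "fisher", "hellinger"),
                       log_base = exp(1), bandwidth = 1, bins = 10) {
  method <- match.arg(method)
  if (!inherits(matrix, "expr_matrix")) matrix <- expr_matrix(matrix)
  if (!is.null(names(labels))) labels <- align_labels(matrix, labels)
  if (length(labels) != ncol(matrix))
    stop_data("labels length (", length(labels),
              ") does not match sample count (", ncol(matrix), ")")
  if (nlevels(factor(labels)) < 2L)
    stop_data("need at least 2 distinct classes to weight features")
  n <- ncol(matrix)
  vals <- unclass(matrix)

  weights <- if (method == "mi") {
    # label-only quantities are shared by every feature
    d <- label_distance_matrix(labels)
    f_y <- rowSums(exp(-d / 2)) / (sqrt(2 * pi) * n)
    log_scale <- log(log_base)
    vapply(seq_len(nrow(vals)), function(i) {
      x <- vals[i, ]
      z <- suppressWarnings(minmax_normalize(x))
      dx <- outer(z, z, `-`) / bandwidth
      f_x <- rowSums(exp(-dx^2 / 2)) / (sqrt(2 * pi) * n)
      f_xy <- rowSums(exp(-sqrt(dx^2 + d) / 2)) / (2 * pi * n)
      w <- mean(log(f_xy / (f_x * f_y))) / log_scale
      if (!is.finite(w))
        stop_data("non-finite weight for feature ", rownames(vals)[i])
      w
    }, numeric(1))
  } else {
    fun <- switch(method,
                  fisher = function(x) fisher_score(x, labels),
                  hellinger = function(x) hellinger_score(x, labels,
                                                          bins = bins))
    vapply(seq_len(nrow(vals)), function(i) {
      w <- suppressWarnings(fun(vals[i, ]))
      if (!is.finite(w))
        stop_data("non-finite weight for feature ", rownames(vals)[i])
      w
    }, numeric(1))
  }

  ord <- order(-weights, seq_along(weights))
  rank <- integer(length(weights))
  rank[ord] <- seq_along(weights)
  out <- data.frame(feature_id = rownames(vals), weight = weights,
                    rank = rank, stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("weight_vector", "data.frame")
  out
}

#' Feature ids in ranking order
#'
#' @param weights A `weight_vector` from [weight_all()].
#' @param n Optionally truncate to the top `n`.
#' @return Character vector of feature ids, best first.
#' @export
ranked_features <- function(weights, n = NULL) {
  ids <- weights$feature_id[order(weights$rank)]
  if (!is.null(n)) ids <- ids[seq_len(min(n, length(ids)))]
  ids
}

#' Write a weight table to TSV
#'
#' Emits `rank`, `feature_id`, `weight` (6 significant digits) sorted by
#' rank, with the weighting method in a `#` comment header.
#'
#' @param weights A `weight_vector`.
#' @param path Output path; written atomically.
#' @param full_precision If `TRUE`, weights are written at full precision.
#' @return The path, invisibly.
#' @export
write_weights <- function(weights, path, full_precision = FALSE) {
  ord <- order(weights$rank)
  w <- weights$weight[ord]
  dt <- data.table::data.table(
    rank = weights$rank[ord],
    feature_id = weights$feature_id[ord],
    weight = if (full_precision) w else signif(w, 6))
  write_atomic(function(tmp) {
    writeLines(paste0("# method=", attr(weights, "method") %||% "mi"), tmp)
    data.table::fwrite(dt, tmp, sep = "\t", quote = FALSE, append = TRUE,
                       col.names = TRUE)
  }, path)
  invisible(path)
}
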