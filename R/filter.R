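#' Total expression of each feature
#'
#' The filtering statistic: the sum of a feature's expression across all
#' samples.
#'
#' @param matrix An [expr_matrix()] or plain numeric matrix
#'   (features x samples).
#' @return Named numeric vector of per-feature totals.
#' @export
total_expression <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop_data("`matrix` must be a numeric matrix")
  rowSums(matrix)
}

#' Chi-square significance threshold for low-expression filtering
#'
#' Under the null hypothesis that a feature is noise, total expression is
#' deemed lowly expressed below
#' \deqn{\theta = \frac{q\,\overline{TE}}{\chi^2_{1-\alpha/2}(q)}}
#' where `q` is the number of features, \eqn{\overline{TE}} the mean total
#' expression and \eqn{\chi^2_{1-\alpha/2}(q)} the chi-square quantile with
#' `q` degrees of freedom at probability \eqn{1-\alpha/2}.
#'
#' @param te Numeric vector of per-feature total expression.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return The threshold `theta` (non-negative scalar).
#' @export
chi2_threshold <- function(te, alpha = 0.05) {
  if (length(te) < 1L) stop_data("`te` must contain at least one feature")
  if (any(!is.finite(te)) || any(te < 0))
    stop_data("`te` must be finite and non-negative")
  assert_scalar_number(alpha, "alpha", 0, 1, open = TRUE)
  q <- length(te)
  q * mean(te) / stats::qchisq(1 - alpha / 2, df = q)
}

#' Remove lowly expressed features by the chi-square null threshold
#'
#' Features whose total expression falls below [chi2_threshold()] are
#' removed; row order of the survivors is preserved. The threshold scales
#' with the data, so the kept set is invariant under global rescaling.
#'
#' @param matrix An [expr_matrix()].
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return A list with `result`, a `filter_result` (fields `te`, `te_mean`,
#'   `alpha`, `theta`, `kept_ids`, `removed_ids`), and `matrix`, the
#'   filtered expression matrix.
#' @export
filter_low_expression <- function(matrix, alpha = 0.05) {
  if (!inherits(matrix, "expr_matrix")) matrix <- expr_matrix(matrix)
  te <- total_expression(matrix)
  theta <- chi2_threshold(te, alpha)
  keep <- te >= theta
  if (!any(keep))
    stop_data("all ", length(te), " features fall below theta = ",
              signif(theta, 6),
              "; check that the input is expression data or use a larger alpha")
  result <- structure(
    list(te = te, te_mean = mean(te), alpha = alpha, theta = theta,
         kept_ids = rownames(matrix)[keep],
         removed_ids = rownames(matrix)[!keep]),
    class = "filter_result")
  filtered <- expr_matrix(unclass(matrix)[keep, , drop = FALSE],
                          unit = expr_unit(matrix))
  list(result = result, matrix = filtered)
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result> theta = ", signif(x$theta, 6),
      " (alpha = ", x$alpha, ")\n",
      "  kept ", length(x$kept_ids), " / ",
      length(x$kept_ids) + length(x$removed_ids), " features\n", sep = "")
  invisible(x)
}

#' Histogram of total expression (reporting utility)
#'
#' Bins the total-expression vector on equal-width bins (width 1 by
#' default) and reports the fraction of features per bin; used to inspect
#' the exponential-like bulk of lowly expressed features. Does not affect
#' filtering.
#'
#' @param te Numeric vector of totals.
#' @param binwidth Bin width (default 1).
#' @param max_te Right edge of the last reported bin (default 35); features
#'   beyond it are pooled into a final open bin.
#' @return A data.frame with `bin_lower`, `bin_upper`, `count`, `ratio`.
#' @export
te_histogram <- function(te, binwidth = 1, max_te = 35) {
  assert_scalar_number(binwidth, "binwidth", 0, Inf, open = TRUE)
  edges <- seq(0, max_te, by = binwidth)
  idx <- pmin(findInterval(te, edges, left.open = FALSE), length(edges))
  counts <- tabulate(idx, nbins = length(edges))
  data.frame(bin_lower = edges,
             bin_upper = c(edges[-1L], Inf),
             count = counts,
             ratio = counts / length(te))
}
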