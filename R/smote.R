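#' SMOTE oversampling to balance class counts
#'
#' Synthetic minority oversampling: each minority class is grown to the
#' majority count by repeatedly picking one of its samples, choosing one of
#' its `k` nearest same-class neighbours (Euclidean), and interpolating
#' with a uniform factor \eqn{u \in [0, 1]} along the segment between them.
#' Original samples are retained; `k` is capped at class size minus one.
#'
#' @param x Numeric matrix, samples in rows, features in columns.
#' @param labels Discrete labels, one per row.
#' @param k Number of nearest neighbours (default 5).
#' @param seed Integer seed for reproducibility; `NULL` uses the current
#'   RNG state.
#' @return A list with `x` (augmented matrix) and `labels` (augmented
#'   factor); synthetic rows are appended after the originals with row
#'   names `<class>_synth_<i>`.
#' @export
smote_balance <- function(x, labels, k = 5, seed = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  labels <- factor(labels)
  if (nrow(x) != length(labels))
    stop_data("labels length (", length(labels),
              ") does not match sample count (", nrow(x), ")")
  counts <- table(labels)
  n_major <- max(counts)
  run <- function() {
    new_x <- list()
    new_y <- list()
    for (cl in levels(labels)) {
      n_c <- counts[[cl]]
      need <- n_major - n_c
      if (need == 0L) next
      if (n_c < 2L)
        stop_data("class '", cl, "' has a single sample and cannot be ",
                  "oversampled; merge it with another class or remove it")
      xc <- x[labels == cl, , drop = FALSE]
      k_c <- min(k, n_c - 1L)
      dmat <- as.matrix(stats::dist(xc))
      diag(dmat) <- Inf
      nn <- do.call(rbind, lapply(seq_len(n_c), function(r)
        order(dmat[r, ])[seq_len(k_c)]))
      base <- sample.int(n_c, need, replace = TRUE)
      pick <- nn[cbind(base, sample.int(k_c, need, replace = TRUE))]
      u <- stats::runif(need)
      synth <- xc[base, , drop = FALSE] +
        u * (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE])
      rownames(synth) <- paste0(cl, "_synth_", seq_len(need))
      new_x[[cl]] <- synth
      new_y[[cl]] <- rep(cl, need)
    }
    if (!length(new_x)) return(list(x = x, labels = labels))
    aug <- rbind(x, do.call(rbind, new_x))
    list(x = aug,
         labels = factor(c(as.character(labels), unlist(new_y)),
                         levels = levels(labels)))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
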