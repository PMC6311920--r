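#' Macro-averaged one-vs-rest ROC AUC
#'
#' Unweighted mean of the per-class one-vs-rest areas under the ROC curve.
#' A class absent from `labels` (or covering all samples) contributes no
#' AUC and is skipped.
#'
#' @param labels True class labels.
#' @param scores Numeric matrix, one column of one-vs-rest decision values
#'   per class, column names are class labels; higher means more likely
#'   that class.
#' @return Macro-AUC in [0, 1] (`NA` if no class is scoreable).
#' @export
macro_auc <- function(labels, scores) {
  labels <- as.character(labels)
  if (is.null(colnames(scores))) stop_data("score columns must be named by class")
  aucs <- vapply(colnames(scores), function(cl) {
    pos <- labels == cl
    if (!any(pos) || all(pos)) return(NA_real_)
    as.numeric(pROC::auc(
      response = factor(pos, levels = c(FALSE, TRUE)),
      predictor = scores[, cl],
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(labels, k, seed) {
  labels <- factor(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop_data("class '", cl, "' has ", length(idx),
                  " samples, fewer than the ", k, " folds required")
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# one-vs-rest RBF SVM decision scores for each class on the test rows
ovr_svm_scores <- function(x_train, y_train, x_test, cost, gamma) {
  classes <- levels(y_train)
  if (is.null(gamma)) {
    v <- stats::var(as.numeric(x_train))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(x_train) * v)
             else 1 / ncol(x_train)
  }
  scores <- matrix(NA_real_, nrow = nrow(x_test), ncol = length(classes),
                   dimnames = list(NULL, classes))
  for (cl in classes) {
    yb <- factor(ifelse(y_train == cl, "pos", "rest"),
                 levels = c("pos", "rest"))
    fit <- e1071::svm(x = x_train, y = yb, kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    pred <- stats::predict(fit, x_test, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # libsvm orients the decision value toward the first training label
    s <- dv[, 1L]
    if (identical(colnames(dv)[1L], "rest/pos")) s <- -s
    scores[, cl] <- s
  }
  scores
}

#' Cross-validated macro-AUC of top-N feature panels
#'
#' For each candidate panel size N: the top-N ranked features are taken,
#' samples are split into stratified folds, SMOTE balancing is applied to
#' the training split of each fold only (never the test split), a
#' one-vs-rest RBF SVM is fitted per class, and the untouched test split is
#' scored by macro-averaged one-vs-rest ROC AUC. Deterministic given
#' `seed`.
#'
#' @param matrix An [expr_matrix()] (features x samples).
#' @param labels Labels named by sample id or ordered like the columns.
#' @param weights A `weight_vector` from [weight_all()] ranking the
#'   matrix's features.
#' @param grid Ascending vector of panel sizes to evaluate; all must be
#'   between 1 and the feature count.
#' @param seed Integer seed controlling fold assignment and SMOTE.
#' @param folds Number of cross-validation folds (default 5); every class
#'   needs at least `folds` samples.
#' @param cost SVM soft-margin cost (default 1).
#' @param gamma RBF kernel width; default `NULL` uses
#'   1 / (n features x overall feature variance).
#' @param smote_k SMOTE neighbour count (default 5).
#' @param smote_before_cv If `TRUE`, balance the full data once before
#'   splitting (leaks synthetic information into test folds; provided to
#'   mimic pipelines that oversample first). Default `FALSE`.
#' @return A data.frame with columns `n`, `mean_auc`, `sd_auc`.
#' @export
evaluate_topn <- function(matrix, labels, weights, grid, seed = 1,
                          folds = 5, cost = 1, gamma = NULL,
                          smote_k = 5, smote_before_cv = FALSE) {
  if (!inherits(matrix, "expr_matrix")) matrix <- expr_matrix(matrix)
  if (!is.null(names(labels))) labels <- align_labels(matrix, labels)
  labels <- factor(labels)
  if (length(grid) < 1L) stop_data("`grid` must contain at least one panel size")
  grid <- as.integer(grid)
  if (any(grid < 1L)) stop_data("panel sizes must be positive")
  if (is.unsorted(grid, strictly = TRUE))
    stop_data("`grid` must be strictly ascending")
  if (max(grid) > nrow(matrix))
    stop_data("largest panel size (", max(grid),
              ") exceeds the feature count (", nrow(matrix), ")")
  ranked <- ranked_features(weights)
  if (!all(ranked %in% rownames(matrix)))
    stop_data("weight table refers to features absent from the matrix")

  x_all <- t(unclass(matrix)[ranked, , drop = FALSE])
  y_all <- labels
  if (smote_before_cv) {
    bal <- smote_balance(x_all, y_all, k = smote_k,
                         seed = derive_seed(seed, 7919))
    x_all <- bal$x
    y_all <- bal$labels
  }
  fold <- stratified_folds(y_all, folds, seed = derive_seed(seed, 1))

  mean_auc <- numeric(length(grid))
  sd_auc <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    n_top <- grid[gi]
    xg <- x_all[, seq_len(n_top), drop = FALSE]
    fold_auc <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      x_train <- xg[tr, , drop = FALSE]
      y_train <- droplevels(y_all[tr])
      if (!smote_before_cv) {
        bal <- smote_balance(x_train, y_train, k = smote_k,
                             seed = derive_seed(seed, 100 * n_top + f))
        x_train <- bal$x
        y_train <- bal$labels
      }
      scores <- ovr_svm_scores(x_train, y_train,
                               xg[!tr, , drop = FALSE], cost, gamma)
      macro_auc(y_all[!tr], scores)
    }, numeric(1))
    mean_auc[gi] <- mean(fold_auc)
    sd_auc[gi] <- stats::sd(fold_auc)
  }
  data.frame(n = grid, mean_auc = mean_auc, sd_auc = sd_auc)
}

#' Choose the panel size where the AUC curve plateaus
#'
#' Returns the smallest N in the grid such that no later grid point
#' improves on its AUC by `epsilon` or more, i.e.
#' \eqn{\max_{N' > N} (AUC(N') - AUC(N)) < \epsilon}. Comparing against
#' all later points (not just N+1) keeps a noisy dip from ending the search
#' early. If no N qualifies (the curve keeps climbing), the argmax is
#' returned with a warning.
#'
#' @param grid Ascending vector of evaluated panel sizes.
#' @param auc Mean macro-AUC per size, same length as `grid`.
#' @param epsilon Plateau tolerance on the AUC scale (default 0.005).
#' @return The chosen panel size (an element of `grid`).
#' @export
select_plateau <- function(grid, auc, epsilon = 0.005) {
  if (length(grid) != length(auc))
    stop_data("`grid` and `auc` must have the same length")
  if (length(grid) < 1L) stop_data("empty grid")
  assert_scalar_number(epsilon, "epsilon", 0, Inf)
  for (i in seq_len(length(grid) - 1L)) {
    later <- auc[seq_along(auc) > i]
    if (max(later) - auc[i] < epsilon) return(grid[i])
  }
  warning("AUC still improving at the largest panel size; returning argmax")
  grid[which.max(auc)]
}

#' Run the full biomarker-panel discovery pipeline
#'
#' Chains the stages: low-expression filtering by the chi-square threshold,
#' per-feature weighting, cross-validated top-N evaluation, and
#' plateau-based panel-size selection. Fully reproducible from
#' (inputs, configuration, seed).
#'
#' @param matrix An [expr_matrix()] of expression values.
#' @param labels Labels named by sample id (or ordered like the columns).
#' @param alpha Filtering significance level (default 0.05); `NULL` skips
#'   the low-expression filter and weights every feature.
#' @param method Weighting method: `"mi"`, `"fisher"` or `"hellinger"`.
#' @param grid Panel sizes to evaluate; default 1 to
#'   `min(grid_max, surviving features)`.
#' @param grid_max Upper end of the default grid (default 50); ignored
#'   when `grid` is given.
#' @param epsilon Plateau tolerance (default 0.005).
#' @param seed Integer seed (default 1).
#' @param log_base,bandwidth,bins Weighting options, see [weight_all()].
#' @param folds,cost,gamma,smote_k,smote_before_cv Evaluation options, see
#'   [evaluate_topn()].
#' @return A `selection_result`: list with `filter` (the `filter_result`),
#'   `weights`, `grid`, `auc`, `auc_sd`, `chosen_n`, `panel` (ordered
#'   feature ids), `method`, `alpha`, `epsilon`, `seed`.
#' @export
run_pipeline <- function(matrix, labels, alpha = 0.05,
                         method = c("mi", "fisher", "hellinger"),
                         grid = NULL, grid_max = 50L, epsilon = 0.005,
                         seed = 1,
                         log_base = exp(1), bandwidth = 1, bins = 10,
                         folds = 5, cost = 1, gamma = NULL,
                         smote_k = 5, smote_before_cv = FALSE) {
  method <- match.arg(method)
  if (!inherits(matrix, "expr_matrix")) matrix <- expr_matrix(matrix)
  if (!is.null(names(labels))) labels <- align_labels(matrix, labels)

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop_data("[", what, "] ", conditionMessage(e)))
  }
  flt <- if (is.null(alpha)) {
    list(result = structure(
           list(te = total_expression(matrix), te_mean = NA_real_,
                alpha = NA_real_, theta = 0,
                kept_ids = rownames(matrix), removed_ids = character()),
           class = "filter_result"),
         matrix = matrix)
  } else {
    stage("filter", filter_low_expression(matrix, alpha = alpha))
  }
  weights <- stage("weight",
                   weight_all(flt$matrix, labels, method = method,
                              log_base = log_base, bandwidth = bandwidth,
                              bins = bins))
  if (is.null(grid)) grid <- seq_len(min(grid_max, nrow(flt$matrix)))
  curve <- stage("evaluate",
                 evaluate_topn(flt$matrix, labels, weights, grid = grid,
                               seed = seed, folds = folds, cost = cost,
                               gamma = gamma, smote_k = smote_k,
                               smote_before_cv = smote_before_cv))
  chosen_n <- stage("select",
                    select_plateau(curve$n, curve$mean_auc,
                                   epsilon = epsilon))
  structure(
    list(filter = flt$result, weights = weights,
         grid = curve$n, auc = curve$mean_auc, auc_sd = curve$sd_auc,
         chosen_n = chosen_n,
         panel = ranked_features(weights, chosen_n),
         method = method, alpha = alpha, epsilon = epsilon, seed = seed),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  i <- match(x$chosen_n, x$grid)
  cat("<selection_result> method = ", x$method, ", seed = ", x$seed, "\n",
      "  filtered: ", length(x$filter$kept_ids), " features kept (theta = ",
      signif(x$filter$theta, 6), ")\n",
      "  panel size: ", x$chosen_n, " (macro-AUC ",
      sprintf("%.3f", x$auc[i]), " +/- ", sprintf("%.3f", x$auc_sd[i]),
      ")\n", sep = "")
  cat("  panel:", paste(utils::head(x$panel, 5), collapse = ", "),
      if (length(x$panel) > 5) "...", "\n")
  invisible(x)
}
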