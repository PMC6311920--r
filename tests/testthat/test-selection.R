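# compact separable dataset used across the selection tests
selection_fixture <- function(n_per_class = c(a = 20, b = 8, c = 12),
                              n_features = 10, sep = 3, seed = 19) {
  withr::with_seed(seed, {
    y <- factor(rep(names(n_per_class), n_per_class))
    n <- length(y)
    vals <- matrix(rexp(n_features * n), nrow = n_features)
    for (j in seq_len(min(3, n_features, length(n_per_class))))
      vals[j, ] <- vals[j, ] + sep * (y == names(n_per_class)[j])
    rownames(vals) <- paste0("f", seq_len(n_features))
    colnames(vals) <- paste0("s", seq_len(n))
    names(y) <- colnames(vals)
    list(matrix = expr_matrix(vals), labels = y)
  })
}

test_that("SMOTE balances class counts with interpolated minority points", {
  fx <- selection_fixture()
  x <- t(unclass(fx$matrix))
  attr(x, "unit") <- NULL
  bal <- smote_balance(x, fx$labels, seed = 3)
  expect_true(all(table(bal$labels) == max(table(fx$labels))))
  expect_equal(nrow(bal$x), length(bal$labels))
  # originals retained verbatim
  expect_equal(bal$x[seq_len(nrow(x)), ], x)

  # already balanced input returned unchanged
  yb <- factor(rep(c("a", "b"), each = 5))
  xb <- matrix(rnorm(20), nrow = 10)
  same <- smote_balance(xb, yb, seed = 1)
  expect_equal(same$x, xb)
  expect_identical(same$labels, yb)
})

test_that("synthetic SMOTE points lie on segments between class neighbours", {
  x <- rbind(c(0, 0), c(1, 1), c(10, 0), c(11, 1), c(10.5, 0.5))
  y <- factor(c("m", "m", "M", "M", "M"))
  bal <- smote_balance(x, y, k = 1, seed = 5)
  synth <- bal$x[bal$labels == "m", , drop = FALSE][-(1:2), , drop = FALSE]
  expect_equal(nrow(synth), 1)
  # with k = 1 the only neighbour pair is (0,0)-(1,1): points obey y = x
  expect_equal(synth[, 1], synth[, 2], tolerance = 1e-12)
  expect_true(all(synth >= 0 & synth <= 1))

  y1 <- factor(c("m", "M", "M", "M", "M"))
  expect_error(smote_balance(x, y1, seed = 1), "single sample")
})

test_that("macro AUC agrees with brute-force pair counting", {
  set.seed(41)
  for (i in 1:10) {
    n <- 30
    y <- sample(c("a", "b", "c"), n, replace = TRUE)
    y[1:3] <- c("a", "b", "c")
    scores <- matrix(rnorm(3 * n), ncol = 3,
                     dimnames = list(NULL, c("a", "b", "c")))
    expect_equal(macro_auc(y, scores), pair_macro_auc(y, scores),
                 tolerance = 1e-12)
  }
})

test_that("top-N evaluation is deterministic and bounded in [0, 1]", {
  fx <- selection_fixture()
  w <- weight_all(fx$matrix, fx$labels, method = "fisher")
  grid <- c(1L, 2L, 3L, 5L)
  a1 <- evaluate_topn(fx$matrix, fx$labels, w, grid, seed = 6)
  a2 <- evaluate_topn(fx$matrix, fx$labels, w, grid, seed = 6)
  expect_identical(a1, a2)
  expect_true(all(a1$mean_auc >= 0 & a1$mean_auc <= 1))
  a3 <- evaluate_topn(fx$matrix, fx$labels, w, grid, seed = 7)
  expect_false(identical(a1$mean_auc, a3$mean_auc))
})

test_that("separable classes reach high AUC; permuted labels hover at 1/2", {
  fx <- selection_fixture(sep = 6)
  w <- weight_all(fx$matrix, fx$labels, method = "fisher")
  a <- evaluate_topn(fx$matrix, fx$labels, w, grid = c(3L, 5L), seed = 2)
  expect_gt(max(a$mean_auc), 0.95)

  perm <- withr::with_seed(4, sample(as.character(fx$labels)))
  names(perm) <- names(fx$labels)
  a0 <- evaluate_topn(fx$matrix, factor(perm), w, grid = c(3L, 5L), seed = 2)
  expect_true(all(abs(a0$mean_auc - 0.5) <= 0.15))
})

test_that("evaluation rejects malformed grids and tiny classes", {
  fx <- selection_fixture()
  w <- weight_all(fx$matrix, fx$labels, method = "fisher")
  expect_error(evaluate_topn(fx$matrix, fx$labels, w, integer(0)), "grid")
  expect_error(evaluate_topn(fx$matrix, fx$labels, w, c(2L, 1L)), "ascending")
  expect_error(evaluate_topn(fx$matrix, fx$labels, w, 99L), "feature count")
  tiny <- selection_fixture(n_per_class = c(a = 12, b = 3))
  wt <- weight_all(tiny$matrix, tiny$labels, method = "fisher")
  expect_error(evaluate_topn(tiny$matrix, tiny$labels, wt, 2L), "folds")
})

test_that("the plateau rule picks the first size no later point beats", {
  expect_equal(select_plateau(1:6, c(0.70, 0.80, 0.85, 0.86, 0.861, 0.862),
                              epsilon = 0.005), 4)
  expect_equal(select_plateau(1:5, rep(0.8, 5)), 1)
  expect_warning(n <- select_plateau(1:4, c(0.5, 0.6, 0.7, 0.8)), "argmax")
  expect_equal(n, 4)
  expect_error(select_plateau(1:3, c(0.5, 0.6)), "length")
})

test_that("the full pipeline returns a coherent selection result", {
  fx <- selection_fixture(n_per_class = c(a = 20, b = 10, c = 14), sep = 6)
  res <- suppressWarnings(
    run_pipeline(fx$matrix, fx$labels, method = "fisher", seed = 3,
                 alpha = NULL, grid_max = 6))
  expect_s3_class(res, "selection_result")
  expect_true(res$chosen_n %in% res$grid)
  expect_length(res$panel, res$chosen_n)
  expect_identical(res$panel,
                   ranked_features(res$weights, res$chosen_n))
  # stage errors carry context
  bad <- fx$labels
  levels(bad) <- rep("one", 3)
  expect_error(run_pipeline(fx$matrix, bad, seed = 1), "\\[weight\\]")
})
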