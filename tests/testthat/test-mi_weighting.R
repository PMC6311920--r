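test_that("min-max normalization maps to [0, 1]", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(z <- minmax_normalize(c(3, 3, 3)), "constant")
  expect_equal(z, c(0, 0, 0))
  set.seed(2)
  r <- minmax_normalize(rnorm(20))
  expect_equal(range(r), c(0, 1))
})

test_that("kernel density estimates match longhand sums on the micro-example", {
  y <- c("A", "B", "A", "B")
  est <- estimate_densities(MICRO_X, y)
  expect_equal(est$f_x, rep(MICRO_F_MARGINAL, 4), tolerance = 1e-12)
  expect_equal(est$f_y, rep(MICRO_F_MARGINAL, 4), tolerance = 1e-12)
  expect_equal(est$f_xy, rep(MICRO_F_JOINT, 4), tolerance = 1e-12)
  # D is a symmetric zero-diagonal mixed distance
  expect_equal(est$D, t(est$D))
  expect_equal(diag(est$D), rep(0, 4))
})

test_that("densities are strictly positive; constant x gives the kernel peak", {
  set.seed(5)
  x <- runif(15)
  y <- sample(letters[1:3], 15, replace = TRUE)
  est <- estimate_densities(x, y)
  expect_true(all(est$f_x > 0) && all(est$f_y > 0) && all(est$f_xy > 0))
  cz <- estimate_densities(rep(0, 10), rep(c("a", "b"), 5))
  expect_equal(cz$f_x, rep(1 / sqrt(2 * pi), 10), tolerance = 1e-12)
  expect_error(estimate_densities(x, y[-1]), "length")
})

test_that("the MI weight reproduces the worked micro-example", {
  expect_equal(mi_weight(MICRO_X, c("A", "B", "A", "B")),
               MICRO_MI_ALIGNED, tolerance = 1e-10)
  expect_equal(mi_weight(MICRO_X, c("A", "A", "B", "B")),
               MICRO_MI_BALANCED, tolerance = 1e-10)
  expect_gt(mi_weight(MICRO_X, c("A", "B", "A", "B")),
            mi_weight(MICRO_X, c("A", "A", "B", "B")))
  expect_error(mi_weight(1, "A"), "at least 2")
})

test_that("a constant feature has weight exactly zero", {
  set.seed(9)
  y <- sample(c("p", "q", "r"), 30, replace = TRUE)
  expect_lt(abs(suppressWarnings(mi_weight(rep(4.2, 30), y))), 1e-12)
})

test_that("the vectorized weighting equals the triple-loop oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    x <- rexp(n) * sample(c(1, 100), 1)
    y <- sample(letters[1:sample(2:4, 1)], n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("a", "b")
    expect_equal(mi_weight(x, y), naive_mi(x, y), tolerance = 1e-10)
  }
})

test_that("weights are invariant to sample order, label names and affine maps", {
  set.seed(13)
  n <- 25
  x <- rlnorm(n)
  y <- sample(c("u", "v", "w"), n, replace = TRUE)
  w0 <- mi_weight(x, y)
  perm <- sample(n)
  expect_equal(mi_weight(x[perm], y[perm]), w0, tolerance = 1e-12)
  renamed <- c(u = "class3", v = "class1", w = "class2")[y]
  expect_equal(mi_weight(x, renamed), w0, tolerance = 1e-12)
  expect_equal(mi_weight(10 + 3.7 * x, y), w0, tolerance = 1e-12)
})

test_that("weight_all ranks deterministically with index tie-breaks", {
  set.seed(17)
  base <- rexp(12)
  y <- rep(c("a", "b"), 6)
  vals <- rbind(const = rep(2, 12), dup1 = base, dup2 = base)
  colnames(vals) <- paste0("s", 1:12)
  w <- weight_all(expr_matrix(vals), y)
  expect_s3_class(w, "weight_vector")
  expect_equal(w$weight[2], w$weight[3], tolerance = 1e-15)
  expect_lt(w$rank[2], w$rank[3])  # tie broken by row index
  expect_equal(w$weight[1], 0, tolerance = 1e-12)
  expect_identical(sort(w$rank), 1:3)
})

test_that("planted informative features outrank noise features", {
  d <- generate_dataset(generator_config(
    n_samples = 120, n_noise = 45, n_informative = 5,
    effect_size = 2.5, dispersion = 0.5, seed = 7))
  w <- weight_all(d$matrix, d$labels)
  ranks <- w$rank[w$feature_id %in% d$truth]
  expect_true(all(ranks <= 8))
})

test_that("label permutation lowers the weight of an informative feature", {
  d <- generate_dataset(generator_config(effect_size = 2.5,
                                         dispersion = 0.5, seed = 2))
  x <- unclass(d$matrix)[d$truth[1], ]
  w_true <- mi_weight(x, d$labels)
  set.seed(11)
  w_perm <- replicate(30, mi_weight(x, sample(as.character(d$labels))))
  expect_gt(w_true, mean(w_perm))
})

test_that("weighting fails cleanly without class contrast", {
  m <- make_expr(matrix(rexp(10), nrow = 2))
  expect_error(weight_all(m, rep("only", 5)), "2 distinct classes")
})
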