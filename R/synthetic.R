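#' Configuration for the synthetic isomiR benchmark generator
#'
#' Defaults emulate the statistical structure of a bulk isomiR expression
#' study of 698 breast-cancer patients in four imbalanced receptor-status
#' subtypes (proportions 472/31/119/76): a large majority of features whose
#' total expression follows an exponential distribution concentrated below
#' 1, plus a small planted set of class-informative features.
#'
#' @param n_samples Number of samples (default 200).
#' @param class_proportions Non-negative class proportions summing to 1;
#'   default the empirical subtype fractions c(472, 31, 119, 76)/698.
#' @param class_names Labels for the classes; default receptor-status
#'   style names.
#' @param n_noise Number of uninformative features (default 480).
#' @param n_informative Number of planted informative features
#'   (default 20).
#' @param noise_te_mean Mean of the exponential distribution of noise
#'   feature totals (default 0.5, putting ~86% of noise totals below 1).
#' @param effect_size Log-scale shift of the informative features in their
#'   assigned class (default 1.0); 0 yields a null dataset.
#' @param dispersion Log-normal sdlog of informative feature expression
#'   (default 1.0).
#' @param base_expression Median per-sample expression of informative
#'   features outside the shifted class (default 2).
#' @param seed Integer seed (default 1).
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_samples = 200,
                             class_proportions = c(472, 31, 119, 76) / 698,
                             class_names = NULL,
                             n_noise = 480, n_informative = 20,
                             noise_te_mean = 0.5, effect_size = 1.0,
                             dispersion = 1.0, base_expression = 2,
                             seed = 1) {
  assert_scalar_number(n_samples, "n_samples", 1, Inf)
  assert_scalar_number(n_noise, "n_noise", 0, Inf)
  assert_scalar_number(n_informative, "n_informative", 0, Inf)
  assert_scalar_number(noise_te_mean, "noise_te_mean", 0, Inf, open = TRUE)
  assert_scalar_number(effect_size, "effect_size", 0, Inf)
  assert_scalar_number(dispersion, "dispersion", 0, Inf, open = TRUE)
  assert_scalar_number(base_expression, "base_expression", 0, Inf,
                       open = TRUE)
  if (any(class_proportions < 0))
    stop_data("class proportions must be non-negative")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop_data("class proportions must sum to 1 (got ",
              sum(class_proportions), ")")
  if (is.null(class_names))
    class_names <- if (length(class_proportions) == 4L)
      c("ERpos_HER2neg", "ERneg_HER2pos", "TripleNeg", "ERpos_HER2pos")
    else paste0("subtype", seq_along(class_proportions))
  if (length(class_names) != length(class_proportions))
    stop_data("need one class name per proportion")
  if (any(class_proportions * n_samples < 2))
    stop_data("every class must have an expected count of at least 2 ",
              "at n_samples = ", n_samples)
  structure(
    list(n_samples = as.integer(n_samples),
         class_proportions = class_proportions,
         class_names = class_names,
         n_noise = as.integer(n_noise),
         n_informative = as.integer(n_informative),
         noise_te_mean = noise_te_mean, effect_size = effect_size,
         dispersion = dispersion, base_expression = base_expression,
         seed = as.integer(seed)),
    class = "generator_config")
}

# deterministic largest-remainder apportionment of n samples to proportions
apportion_counts <- function(n, proportions) {
  raw <- proportions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

# unique syntactically valid isomiR-style feature names
synth_feature_names <- function(n, prefix) {
  ends <- c("5p", "3p")
  marks <- c("3′", "5′")
  codes <- c("t", "a")
  sprintf("hsa-mir-%s%04d-%s |%s%s-%d",
          prefix, seq_len(n),
          sample(ends, n, replace = TRUE),
          sample(marks, n, replace = TRUE),
          sample(codes, n, replace = TRUE),
          sample.int(3, n, replace = TRUE))
}

#' Generate a synthetic isomiR expression benchmark
#'
#' Labels are apportioned deterministically to the configured proportions
#' and shuffled. Noise features draw a total expression from
#' Exponential(mean = `noise_te_mean`) and spread it across samples by
#' normalized log-normal(0, `dispersion`) weights, so their totals
#' reproduce the exponential bulk below 1 while their per-sample shape
#' matches the informative features: at `effect_size = 0` a planted
#' feature and a noise feature are indistinguishable after per-feature
#' min-max normalization. Informative features are log-normal
#' (`meanlog = log(base_expression)`, `sdlog = dispersion`) with the
#' meanlog raised by `effect_size` in one assigned class; classes are
#' assigned round-robin so each subtype receives its share of markers.
#' All feature names parse with [parse_isomir_name()].
#'
#' @param config A [generator_config()].
#' @return A list with `matrix` (an [expr_matrix()], unit `"rpm"`),
#'   `labels` (named factor) and `truth` (character vector of planted
#'   informative feature ids).
#' @export
generate_dataset <- function(config = generator_config()) {
  if (!inherits(config, "generator_config"))
    stop_data("`config` must come from generator_config()")
  with_seed(config$seed, {
    n <- config$n_samples
    counts <- apportion_counts(n, config$class_proportions)
    labels <- factor(sample(rep(config$class_names, counts)),
                     levels = config$class_names)
    sample_ids <- sprintf("sample_%03d", seq_len(n))
    names(labels) <- sample_ids

    info_ids <- if (config$n_informative > 0)
      synth_feature_names(config$n_informative, "i") else character()
    noise_ids <- if (config$n_noise > 0)
      synth_feature_names(config$n_noise, "n") else character()

    rows <- vector("list", config$n_informative + config$n_noise)
    k_classes <- length(config$class_names)
    mu0 <- log(config$base_expression)
    for (j in seq_len(config$n_informative)) {
      cl <- config$class_names[((j - 1L) %% k_classes) + 1L]
      shift <- config$effect_size * (labels == cl)
      rows[[j]] <- stats::rlnorm(n, meanlog = mu0 + shift,
                                 sdlog = config$dispersion)
    }
    for (j in seq_len(config$n_noise)) {
      te <- stats::rexp(1L, rate = 1 / config$noise_te_mean)
      w <- stats::rlnorm(n, meanlog = 0, sdlog = config$dispersion)
      rows[[config$n_informative + j]] <- te * w / sum(w)
    }
    values <- do.call(rbind, rows)
    rownames(values) <- c(info_ids, noise_ids)
    colnames(values) <- sample_ids
    list(matrix = expr_matrix(values, unit = "rpm"),
         labels = labels,
         truth = info_ids)
  })
}
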