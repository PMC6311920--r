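# isomiRpanel

Discovery of compact isomiR biomarker panels that classify disease
subtypes from bulk small-RNA expression profiles.

IsomiRs — 3′/5′ trimming and addition variants of mature miRNAs — carry
subtype information in cancer cohorts, but a typical quantification holds
tens of thousands of features, most of them noise-level, under strongly
imbalanced subtype labels. `isomiRpanel` implements a three-stage
pipeline for this setting:

1. **Low-expression filtering.** With per-feature total expression
   $te_\tau = \sum_a x_\tau^a$ over samples, features are removed below
   the chi-square null-hypothesis threshold

   $$\theta = \frac{q\,\overline{TE}}{\chi^2_{1-\alpha/2}(q)},
     \qquad \alpha = 0.05,$$

   where $q$ is the feature count and $\overline{TE}$ the mean total.

2. **Kernel-density mutual-information weighting.** Each surviving
   feature $x$ (min-max normalized) is scored against the discrete
   labels $Y$ by the plug-in estimator
   $I(x, Y) = \tfrac1n \sum_i \log f(x_i,y_i) / (f(x_i) f(y_i))$, with
   Gaussian-kernel marginals and a joint kernel coupling the continuous
   feature to the labels through the 0/1 label metric
   $d(y_i,y_j)$. Fisher-score and Hellinger-distance weightings are
   available as baselines.

3. **Panel-size selection.** Top-$N$ panels are scored by stratified
   5-fold cross-validation with SMOTE balancing inside the training
   folds, one-vs-rest RBF SVMs, and macro-averaged one-vs-rest ROC AUC;
   the panel size is chosen where the AUC curve plateaus.

A seeded synthetic-data generator reproduces the field's statistical
structure (exponential bulk of lowly expressed features, a small planted
informative set, imbalanced 4-subtype labels) so the full pipeline is
testable without any data download. The methods vignette
(`vignettes/isomir-panel-selection.Rmd`) documents the model, the
parameter defaults and the design decisions.

## Worked example

```r
library(isomiRpanel)

parse_isomir_name("hsa-miR-21-5p | 3′t-2")
#> <isomir_id> hsa-miR-21-5p |3′t-2
#>   parent: hsa-miR-21-5p
#>   variant: 2 nt trim at the 3′ end

d <- generate_dataset(generator_config(seed = 1))   # 500 features x 200 samples
flt <- filter_low_expression(d$matrix)
flt$result
#> <filter_result> theta = 33.7674 (alpha = 0.05)
#>   kept 20 / 500 features

res <- run_pipeline(d$matrix, d$labels, seed = 1)
res
#> <selection_result> method = mi, seed = 1
#>   filtered: 20 features kept (theta = 33.7674)
#>   panel size: 20 (macro-AUC 0.903 +/- 0.047)
#>   panel: hsa-mir-i0019-5p |3′t-3, hsa-mir-i0016-3p |5′a-2, ...

sum(res$panel %in% d$truth)
#> [1] 20
```

The filter's threshold (here θ ≈ 33.8) removes the 480 noise features
whose exponential totals sit far below it; the chosen panel of 20
recovers all 20 planted informative features at a cross-validated
macro-AUC of 0.90.

## Command line

A thin wrapper over the same functions ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "isomir_panel.R", package = "isomiRpanel"))')
Rscript "$CLI" synth  --seed 1                                   # matrix/labels/truth TSVs
Rscript "$CLI" filter --matrix matrix.tsv --report filter.tsv
Rscript "$CLI" weight --matrix matrix.tsv --labels labels.tsv --method mi
Rscript "$CLI" run    --matrix matrix.tsv --labels labels.tsv --outdir out
```

`run` writes `auc_curve.tsv` (N, mean and SD of macro-AUC), `panel.tsv`
(rank, feature id, weight) and `summary.json` (θ, chosen panel size,
configuration echo). A YAML file passed as `--config` supplies defaults;
flags override it. Exit codes: 0 success, 2 usage error, 1 data error.

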