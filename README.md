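# cmcmarkers

Neuromechanical markers of balance and functional mobility after
stroke: corticomuscular coherence (CMC) and centre-of-pressure (COP)
feature extraction from a sway-referenced continuous balance task, and a
two-stage machine-learning pipeline — classification-based feature
selection followed by regression — predicting the Berg Balance Scale
(BBS, 0–56) and the Timed Up and Go time (TUG, seconds).

The package is aimed at motor-control and rehabilitation researchers who
want a reproducible, fully tested implementation of this analysis. No
public recording of the paradigm exists, so the package includes a
first-class synthetic cohort generator that emulates the study design
(18 stroke + 15 healthy subjects; six 20-s trials at platform gains
0, 0.6, −0.4, 0, 1.0, −1.0; one Cz-equivalent EEG channel at 250 Hz, ten
EMG channels at 1111.11 Hz, COP traces at 100 Hz; outcomes generated
from named ground-truth features; trials lost to falls).

## The methods in brief

* **Wavelet CMC.** Morlet CWT (ω₀ = 6, 10 scales/octave over
  0.05–50 Hz), smoothed magnitude coherence
  `|S(W_x W_y*)|² / (S|W_x|² · S|W_y|²)`, cone-of-influence masking,
  averaging over 2-s bins (9 per 18-s window, 7 after edge exclusion),
  band means (delta…gamma), Fisher z-transform. Significance: the
  closed form `Z = 1 − α^{1/(L−1)}` with `L = 6 × 7 = 42` segments
  (Z ≈ 0.07 at α = 0.05), calibrated against a matched segment-pooled
  estimator and Monte-Carlo surrogates.
* **Composite CMC indices.** Asymmetry index `(a−b)/(a+b)` between
  sides, task-modulation index between difficulty levels, and band AUC
  (trapezoidal integral of the coherence spectrum).
* **Posturography.** COP mean/SD/RMS/velocity/sample-entropy per
  direction, path-length statistics, and the 95% confidence ellipse
  area `π · χ²₍₂,0.95₎ · √det Σ` (χ² ≈ 5.991).
* **Stage 1.** 528-feature table (fixed registry), group-stratified KNN
  imputation with a t-test-based choice of k, stratified 24/9 split,
  seven classifier families × three seeds, Shapley-attribution
  consolidation (retain features non-zero in ≥ 4 of 6 top-two-family
  runs), 2-D embedding of the retained set.
* **Stage 2.** Gradient-boosted-tree and elastic-net regression of BBS
  and TUG on the retained predictors; R², adjusted R², RMSE, MAE,
  F statistics; Shapley rankings and Bonferroni-corrected Spearman
  correlations with the predicted scores.

See the methods vignette (`vignettes/methods.Rmd`) for the model
assumptions, numerical choices and limitations.

## Worked example

```r
library(cmcmarkers)

# significance threshold for 6 trials x 7 usable 2-s bins
significance_threshold(42, alpha = 0.05)
#> [1] 0.07046112

# a coupled EEG/EMG-like pair with in-band snr 5 in the beta band
pr <- generate_coupled_pair(snr = 5, band = c(12, 30), rng_seed = 1)
res <- wavelet_coherence(pr$x, pr$y)
band_average(bin_average(res), "beta")
#> [1] 0.7296612   # expected ~ 1/(1 + 1/5)^2 plus the estimator floor
autoplot(res)

# full pipeline on a synthetic cohort
run <- run_pipeline(pipeline_config(truth_seed = 7, out_dir = "out"))
run$stage1$summary
#> # A tibble: 7 x 3
#>   family mean_auc sd_auc
#>   <chr>     <dbl>  <dbl>
#> 1 enet        1        0
#> 2 rf          1        0
#> 3 gbt         1        0
#> 4 l1          1        0
#> 5 l2          1        0
#> 6 ada         0.8      0
#> 7 svm         1        0
glance(run$stage2)
#> # A tibble: 4 x 5
#>   family target test_rmse test_r2 test_mae
#>   <chr>  <chr>      <dbl>   <dbl>    <dbl>
#> 1 gbt    bbs         4.18   0.392     2.80
#> 2 enet   bbs         1.99   0.863     1.54
#> 3 gbt    tug         5.24   0.693     3.14
#> 4 enet   tug         3.28   0.880     2.85
```

Stage 1 selects the elastic net and the random forest as the top two
families (several families tie at AUC 1 on the strongly separated
synthetic cohort; the registration order pairs the sparse linear
selector with the dense bagged ensemble), retains 37 features present
in at least 4 of the 6 top-family runs, and stage 2 predicts BBS/TUG
from the retained predictors (BBS and TUG themselves are excluded).

`run_pipeline()` writes a report bundle (feature table + schema sidecar,
stage reports as JSON/CSV, embedding coordinates, manifest with
checksums). A thin command-line wrapper is installed at
`inst/scripts/run_pipeline.R`.

The numbers above are what the pipeline printed for that seed on the
synthetic cohort; stage-1 AUCs are near-perfect by construction (strong
planted effects) and stage-2 test errors are small relative to the BBS
(0–56) and TUG (7–60 s) scales because the outcomes are generated from
the planted features.

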