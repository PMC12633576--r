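---
title: "Methods: corticomuscular coherence and sway markers of balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corticomuscular coherence and sway markers of balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Clinical balance scores after stroke -- the Berg Balance Scale (BBS,
0--56, higher is better) and the Timed Up and Go test (TUG, seconds,
longer is worse) -- are rater- and effort-dependent. The pipeline in this
package implements a candidate set of *objective* neuromechanical markers
recorded during a sway-referenced continuous balance task, and a
two-stage machine-learning procedure that asks which of those markers
predict BBS and TUG:

1. **Corticomuscular coherence (CMC).** Morlet wavelet coherence between
   a sensorimotor EEG channel (Cz) and surface EMG of five lower-limb
   muscles bilaterally (tibialis anterior TA, gastrocnemius medialis GM,
   soleus SOL, rectus femoris RF, biceps femoris BF), summarised per
   frequency band (delta 0.05--4, theta 4--8, alpha 8--12, beta 12--30,
   gamma 30--50 Hz) and per task-difficulty condition, plus composite
   indices: the asymmetry index `AI = (a - b)/(a + b)` between the
   affected/dominant and less-affected/nondominant sides, the task
   modulation index (same contrast between difficulty levels), and the
   band AUC (trapezoidal integral of the coherence spectrum).
2. **Posturography.** Centre-of-pressure (COP) summary statistics per
   direction (mean, SD, RMS about the trial mean, mean absolute velocity,
   sample entropy), path-length statistics of the resultant increment
   series, and the 95% confidence ellipse area
   `pi * chi^2_(2, 0.95) * sqrt(det Sigma)`.
3. **Two-stage modelling.** Stage 1 classifies stroke vs healthy with
   seven model families across three seeds and uses consolidated Shapley
   attributions for feature selection (retention when non-zero in at
   least 4 of the 6 top-two-family runs). Stage 2 regresses BBS and TUG
   on the retained predictors and reports metrics, Shapley rankings and
   Bonferroni-corrected Spearman correlations between predictors and
   predicted scores.

No public recording of this paradigm exists, so the package ships a
fully synthetic cohort generator whose statistical structure matches the
study design; everything downstream is exercised and tested against it.

# The synthetic cohort

`ground_truth()` fixes the generator. The design emulates:

* **33 subjects** (18 stroke, 15 healthy; ages truncated-normal at the
  study's group means/SDs), six 20-s trials per subject at platform
  gains `0, 0.6, -0.4, 0, 1.0, -1.0`, mapped deterministically to low /
  medium / high difficulty. Trials are dropped independently with a
  per-(group, difficulty) fall probability (up to 25% for stroke at high
  difficulty), which produces the missing feature cells the imputation
  stage exists for.
* **Band-specific EEG--EMG coupling.** Each muscle couples to the EEG in
  one characteristic band (TA delta, SOL theta, GM/RF/BF beta) through a
  shared band-limited Gaussian source with independent white channel
  noise. The coupling strength is an in-band source-to-noise variance
  ratio `snr`; for an isolated pair the expected magnitude coherence has
  the closed form `1 / (1 + 1/snr)^2`, which the tests use as an oracle.
  Group effects are deliberately *concentrated*: a four-fold
  affected-side drop for TA (medium difficulty) and SOL (medium), a
  compensatory less-affected increase for SOL and BF, a high-difficulty
  less-affected modulation failure for RF, and no effect at all for GM
  (a negative control). Concentration matters: with diffuse effects every
  one of the ~500 coherence columns separates the groups and sparse
  selectors retain arbitrary correlates rather than the generating
  features, which would make parameter recovery meaningless.
* **Sway.** COP traces are Ornstein-Uhlenbeck (AR(1)) processes with a
  1-s correlation time and difficulty-graded stationary amplitude
  (0.25--0.8 cm); stroke subjects sway ~2x more medio-laterally under
  high difficulty, and nowhere else -- again so that the generating
  feature (`COP_ML_rms_highcomb`) is identifiable.
* **Outcomes.** BBS and TUG are generated from *named* ground-truth
  feature values through fixed linear weights:
  `BBS = round(56 * plogis(eta))` and `TUG = exp(eta')` clamped to
  7--60 s, with Gaussian noise on the linear scales. The weighted
  features mirror the marker families the analysis highlights (TA delta
  AUC, SOL theta asymmetry, ML sway RMS for BBS; BF beta asymmetry, ML
  sway RMS, TA delta AUC and RF beta task modulation for TUG). The
  standardisation constants in `feature_scaling` are fixed population
  values of the generator, not estimated per cohort, so single-subject
  cohorts are well-defined and outcomes do not depend on cohort
  composition.

What the generator does **not** emulate: real EEG artifacts (ocular,
line noise, motion), nonstationarity within trials, EMG amplitude
modulation / rectified-envelope coupling, 1/f background spectra, or
floor/ceiling behaviour of clinical raters. Passing tests therefore
demonstrate that the *pipeline* recovers known structure, not that the
markers behave identically on human data.

# EMG conditioning and why phase handling matters

`condition_emg()` detrends, applies the acquisition-style 20--450 Hz
Butterworth band-pass (second-order edges) as a *single causal pass*, and
resamples 1111.11 -> 250 Hz by exact FFT-domain resampling of the
mirror-extended signal (brick-wall anti-aliasing, no imaging).

Two numerical choices here are load-bearing:

* Magnitude coherence is invariant to linear filtering of one channel,
  so a causal filter's phase lag is harmless. Applying the band-pass
  forward-backward instead would *square* the stop-band attenuation,
  pushing sub-20 Hz content to ~1e-16 of full scale -- below double
  precision relative to the broadband signal -- and delta/theta coherence
  would be numerically destroyed. The single-pass second-order edge
  leaves a clean -30 to -40 dB low-frequency residue, which is exactly
  why low-band CMC remains estimable after band-pass acquisition.
* Interpolation-based resampling creates spectral images of pass-band
  content (~1e-2..1e-3) that would bury that residue; FFT resampling of
  the mirror-extended signal creates none.

`estimate_com()` (COP -> centre of mass, 2nd-order Butterworth low-pass
at 0.86 Hz) *is* applied forward-backward with mirrored padding: the COM
estimate must not lag the COP, and its pass band is far from any
numerical floor. Filtering is per trial.

# Wavelet coherence

`wavelet_coherence()` computes the Morlet CWT (centre frequency
`omega0 = 6`) on a grid of 10 scales per octave covering 0.05--50 Hz
(101 scales), over the first 18 s of each trial (4500 samples at
250 Hz). Coherence is

    |S(Wx conj(Wy) / s)|^2 / ( S(|Wx|^2 / s) * S(|Wy|^2 / s) )

where `S` is time smoothing with a scale-proportional Gaussian
(sd = one scale) followed by a boxcar over 0.6 octave of scales -- the
de-facto standard smoothing for Morlet coherence. Without `S` the ratio
is identically 1 (`smooth = FALSE` exposes this sanity check). Numerics:

* The Gaussian is realised as three variance-matched box passes (O(n)).
* Each scale is synthesised on a power-of-two decimated grid chosen so
  the daughter spectrum stays below the decimated Nyquist -- an exact
  subsampling of the full-rate transform -- smoothed there, and linearly
  interpolated back for the scale boxcar and the ratio. Smoothed fields
  vary on the scale of the wavelet, several times the decimation step,
  so the interpolation error is negligible.
* Cells inside the cone of influence (edge distance < sqrt(2) * scale)
  are the only ones used by every averaging step; scales whose period
  exceeds what the window resolves are thereby fully masked rather than
  dropped from the band. With an 18-s window this limits the usable
  delta band to about 0.15 Hz upwards.
* The feature pipeline evaluates the coherence map on a 5-sample stride
  (50 Hz): bin means of fields smoothed over at least one wavelet scale
  are unchanged to well below estimator noise, at a 5x cost saving.

Coherence maps are averaged over nine non-overlapping 2-s bins; the
first and last bins are edge-contaminated and dropped, leaving 7 usable
bins per trial; with 6 trials this gives L = 42 segments. Band values
are unweighted means over in-band, in-COI cells, averaged across the
trials of a condition and then Fisher z-transformed (`atanh`, input
clipped at 1 - 1e-10). Averaging before transforming follows the order
in which the quantities are defined; composite indices (AI, TMI) are
computed from the condition-level Fisher-z values.

# Significance calibration

The closed-form threshold `Z = 1 - alpha^(1/(L-1))` is the null
(1 - alpha) quantile of coherence *pooled over L independent segments*
(Goodman's law). The smoothed bin-mean coherence map is a different,
biased estimator: its null level is set by the smoothing span (a noise
floor around 0.25--0.3 per cell), so comparing bin-mean values to Z
would be mis-calibrated by construction. The package therefore exposes a
matched estimator, `pooled_band_coherence()`: per scale, one wavelet
coefficient at the centre of each usable 2-s bin (bin centres are at
least one wavelet decorrelation length apart above ~1.5 Hz), with cross-
and auto-spectra pooled over the L bins. For independent inputs its
exceedance rate over `significance_threshold(L)` is alpha, which the
acceptance suite verifies empirically over 500 Monte-Carlo replicates at
L = 42. `monte_carlo_significance()` estimates per-scale thresholds from
AR(1) surrogates matched to the inputs' lag-1 autocorrelation and
defaults to the same pooled statistic, so its thresholds converge to the
closed form for matched L. Feature extraction keeps the bin-mean map:
its values are used comparatively (between groups, sides and
conditions), not against Z.

# Feature table, imputation, and the two-stage models

The feature table follows a fixed 528-column registry
(`feature_registry()`): 150 band-CMC columns, 75 AI, 100 TMI, 150 AUC,
15 + 15 COP summaries (AP/ML), 15 path-length, 3 ellipse areas, and the
subject, group (0 = stroke, 1 = healthy), age, BBS and TUG columns.
Conditions pool trials of equal difficulty (low = the two gain-0 trials,
medium = {0.6, 1.0}, high = {-0.4, -1.0}); per-trial statistics are
averaged within condition, and a condition with no surviving trial
yields missing features.

Missing cells are imputed by group-stratified KNN
(`impute_features()`): within each group, distances are nan-aware
Euclidean over standardised mutually observed features and a missing
cell takes the mean of its k nearest donors. k is chosen from
{1, 3, 5, 7, 9} to minimise the number of columns whose imputed values
deviate from the pre-imputation group mean (one-sample t-test,
p < 0.05), ties towards larger k; columns with a single imputed cell are
untestable and not counted. Imputation precedes the train/test split --
as in the study design it follows -- so the leakage guarantee covers
standardisation, tuning and fitting (corrupting test labels after
imputation provably changes nothing fitted), not the imputation itself.

Stage 1 splits 33 subjects 24/9 by a stratified 75/25 split (largest-
remainder allocation, split seed 42) and tunes seven families by
3-fold stratified CV on ROC AUC: penalised logistic models (elastic net
alpha 0.5, L1, L2; glmnet), gradient-boosted trees and a random forest
(xgboost; the forest as one round of 50--200 parallel trees with
bootstrap rows and sqrt-p per-node columns, which keeps exact TreeSHAP
available for every tree family), AdaBoost over decision stumps (an
in-package SAMME implementation with staged margins), and an SVM
(linear/RBF; e1071). CV AUC ties are endemic on 8-sample folds, so ties
break by validation log-loss and then stable grid order; the
boosted-tree family subsamples rows (0.8) and columns per node (0.3) --
this is what makes the three model seeds (42, 100, 123) meaningful and
spreads tree splits across correlated feature clusters. BBS and TUG are
deliberately *included* as stage-1 inputs (they discriminate the groups)
and excluded again as stage-2 predictors.

Top-two selection ranks families by mean test ROC AUC, ties by smaller
SD and then by a fixed registration order. With well-separated groups
several families routinely tie at AUC 1 on the 9-sample test set, so the
registration order effectively chooses the consolidation pair; it is
fixed as (elastic net, random forest, ...) because the retention rule
needs two *complementary* attribution profiles: the penalised linear
model contributes a sparse, stable support, while the bagged forest
(random per-node subspaces) spreads exact TreeSHAP support across whole
clusters of correlated features. A boosted ensemble on 24 separable rows
saturates after a handful of splits and attributes to fewer than a dozen
columns, which would reduce the consensus to that accidental handful.

Shapley attributions are exact per family: closed-form
`coef * (x - background)` for linear models, TreeSHAP (`predcontrib`)
for tree ensembles, the exact per-feature decomposition for the additive
stump ensemble, and a sampling kernel estimator (`kernel_shap()`, exact
by enumeration up to 10 features) for the SVM. A feature counts as
"present" in a run when its mean absolute attribution over train + test
exceeds 1e-10; features present in >= 4 of the 6 top-two-family runs are
retained. The retained set is embedded in 2-D for visualisation by
classical multidimensional scaling of Euclidean distances on
standardised features -- a deterministic embedding that fulfils the
visualisation-only role here.

Stage 2 (seed 42, 5-fold CV, same split) fits gradient-boosted trees and
elastic-net linear regression (alpha in {0.1, 0.5, 0.9}, lambda in
{0.01, 0.1, 1, 10}) per target. Metrics: R^2, adjusted R^2
(`1-(1-R^2)(n-1)/(n-p-1)`, undefined on the 9-sample test set with 13
predictors and reported as missing with a warning), RMSE, MAE, and the
regression-ANOVA F statistic with p-value (meaningful on the training
fit; reported for completeness elsewhere). Spearman correlations between
each predictor and the predicted score are computed over all 33 subjects
(pooled; the train-only variant is an option) with asymptotic
tie-corrected p-values and a Bonferroni multiplier equal to the number
of predictors.

# Problem sizes used by the test suite

The suite regenerates everything from code: unit fixtures use 2--6
subject cohorts; the calibration property uses 500 Monte-Carlo
replicates of 6-trial white-noise pairs at a mid-band scale; the
coupling-monotonicity property uses a 4-point snr grid with 6 trials per
point; and the recovery property runs the full pipeline (33 subjects,
default generator) over 10 cohort seeds, asserting test ROC AUC >= 0.9
and significance flags plus top-half Shapley rank for every
outcome-generating feature in at least 70% of seeds. These sizes are the
package's reference experiment; they complete on a single CPU in well
under half an hour.

# Known limitations

* The generator's couplings are stationary and purely additive; real
  CMC is nonstationary and partly driven by amplitude modulation that
  linear coherence only partially captures.
* The bin-mean coherence estimator has a smoothing-determined noise
  floor (~0.3), so absolute coherence values are biased upwards; all
  downstream use is comparative. The pooled estimator should be used for
  significance statements.
* With 528 collinear features and n = 33, the retained feature set is a
  representative, not exhaustive, description of group differences;
  near-duplicate columns (e.g. COP RMS vs SD) are interchangeable from
  the selectors' point of view.
* Sub-0.15 Hz delta cells are outside the cone of influence of an 18-s
  window and never contribute; band-AUC integrals for delta effectively
  start near 0.15 Hz.
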