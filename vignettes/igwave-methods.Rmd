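---
title: "Models and methods behind igwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind igwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

igwave analyzes serum IgG autoantibody reactivity profiles measured on
full-length protein arrays: thousands of antigens (features) by dozens to
hundreds of sera (arrays), with per-sample age, sex and diagnosis. This
vignette explains the statistical models at each stage, the tunable
parameters and their defaults, what the synthetic-cohort generator does and
does not emulate, and the numerical and design choices that were genuinely
open. It states no empirical claim that the package's test suite and
acceptance script do not themselves compute.

## Preprocessing

Raw fluorescence is modeled per array as the convolution `X = B + S` with
optical background `B ~ Normal(mu, sigma^2)` and signal
`S ~ Exponential(mean alpha)`. The parameters are estimated per array by
saddle-point-approximated maximum likelihood (limma's normexp machinery;
a method-of-moments estimator matching the first three moments of the
convolution is the fallback when the likelihood fit fails), and each value
is replaced by the posterior mean

    E[S | X = x] = mu.sx + sigma^2 * phi(mu.sx / sigma) / Phi(mu.sx / sigma),
    mu.sx = x - mu - sigma^2 / alpha,

which is strictly positive and strictly increasing in `x`, so the
subsequent log10 is always defined and within-array ranks are preserved.
Between arrays, quantile normalization maps every value to the cross-array
mean of its rank's order statistics; ties within a column receive the
average of their tied ranks' reference values (dialects differ on ties;
this is the limma dialect). The chain is strictly ordered — raw, background
corrected, quantile normalized, log10 — and `profile_matrix` stage tags
enforce it. Missing values are rejected, never imputed: protein-array
exports are complete matrices.

A documented limitation, quantified by the acceptance script
(`age_slope_bias_percent`): when true signal is log-normal and overlaps the
background distribution — exactly the regime the synthetic generator
produces with its defaults (background 500 +/- 50 versus median signal
around 10^3) — the fitted background mean absorbs part of the signal's low
tail. The resulting over-subtraction stretches log-scale differences for
near-background features and inflates fitted age slopes by roughly 15-25%
(background correction alone about +30%; quantile normalization pulls back
about 10 points). This is a property of the model combination, not of the
estimation: it does not shrink as arrays grow. Effect *detection* is
unaffected in direction and ranking; effect *sizes* of dim features should
be read with this in mind.

## Per-feature association models

For every feature the package fits, by ordinary least squares,

    level ~ intercept + age + sex            (aging signature)
    level ~ intercept + diagnosis + age + sex (disease signature)

with sex coded female = 0 / male = 1 and diagnosis control = 0 / case = 1.
Each term is summarized by its type-II sum of squares — the residual-SS
difference between the full model and the model omitting the term (for
these additive models the nested-model definition and the classical
type-II computation coincide, and the test suite asserts equality against
`car::Anova(type = 2)`) — the per-term F statistic
`(SS_term / df_term) / (SS_error / df_error)`, its p-value, and partial eta
squared `SS_term / (SS_term + SS_error)`. Benjamini–Hochberg adjustment is
applied across features separately within each term, because significant
counts are reported per term. The design matrix is shared by all features,
so the fits are vectorized through one QR decomposition per model — the
association stage is effectively instantaneous even at array scale.
Disease cohorts are compared against equal-sized sex- and age-matched
control groups selected by `match_controls`: greedy 1:1 nearest-age
matching within sex, without replacement, processing hard-to-match cases
first (largest distance to the same-sex pool's median age) with seeded
tie-breaks. The matching algorithm is a package choice; "sex- and
age-matched" admits many schemes, and this one is deterministic,
reproducible, and provably no worse in mean absolute age difference than
random same-sex assignment (a property test checks this by simulation).

## Trajectory clustering

Age trajectories are built from z-scored feature levels smoothed by LOESS
(local quadratic fits, tricube weights) of z-score on age and evaluated on
a common uniform 50-point grid over the observed age range, so Euclidean
distances between features are defined on identical support. Features are
clustered by complete-linkage agglomeration of those distances and the
tree is cut at `k` clusters.

* `span = 0.75` (default, exposed): cluster shapes depend on it; smaller
  spans track undulation more closely but admit noise.
* `k = 6` (default): the cluster count is a user choice, not selected by
  any automatic criterion.
* Clustering LOESS-fitted curves is the default; clustering raw z-score
  vectors (`on = "zscores"`) is available, since smoothing-then-clustering
  and clustering-then-smoothing are both defensible readings of standard
  practice.
* Constant features (zero variance) are excluded with a warning rather
  than propagated as NaN.

Complete linkage with a fixed small `k` is fragile in one specific way
that the acceptance checks quantify (`trajectory_mean_adjusted_rand`):
an extreme noise feature can claim a cluster of its own, forcing two true
shape families to merge. With six planted templates of amplitude 0.5
log10 units against residual SD 0.2, mean recovery is adjusted Rand about
0.9 with occasional seeds near 0.75 for exactly this reason.

## Sliding-window wave detection

The scan slides a 20-year window in 1-year steps. At center age `t`, age
is binarized into the low parcel `[t - 10, t)` and the high parcel
`[t, t + 10]` — the shared endpoint goes to the high parcel; the
convention is half-open and documented because verbal descriptions such as
"30–40 versus 40–50" leave it ambiguous — and every feature is tested with
`level ~ binarized_age + sex`. P-values are BH-adjusted across features
within each window (the per-window reading; a global-adjustment option
exists for sensitivity analysis), and the per-center count of q < 0.05
features forms the profile. Windows with fewer than `min_per_parcel = 5`
samples in either parcel are skipped, not padded.

Waves are plateau-aware strict local maxima of that profile: a maximal run
of equal counts higher than both neighbors is one peak, reported at the
floor of the run's midpoint (a two-center plateau therefore reports the
earlier age). Peaks closer than `min_separation = 8` years are merged,
keeping the larger count (ties keep the earlier age), and peaks with fewer
than `min_count = 5` significant features are discarded so that isolated
per-window false discoveries — which the BH guarantee makes expected —
cannot register as waves.

Two quantitative caveats, both computed by the test suite and acceptance
script rather than asserted from theory alone:

1. *Localization degrades as effects strengthen.* A step change reaching
   BH significance even when the window straddles it by several years
   saturates the count profile into a plateau of roughly twice the parcel
   width; neighboring waves (e.g. 12 years apart) can then merge into a
   single hump peaking between them. With strong steps (about 3 residual
   SD) planted at 30/50/62, end-to-end recovery of all three peaks to
   within +/-2 years succeeds in roughly 75-90% of runs
   (`wave_recovery_success_fraction`); with moderate steps (under 1 SD)
   localization is essentially exact. Count-based peak detection is a
   detector of *onsets of change*, sharpest when significance is marginal.
2. *A fully clean null profile is not the correct expectation.* Under the
   global null, BH makes at least one false discovery per window with
   probability equal to the FDR level (0.05). A profile of ~40 partially
   correlated windows is therefore fully clean only a minority of the
   time; the calibrated quantity is the per-window clean fraction, which
   sits at the nominal 95% (`null_clean_window_fraction`).

## Enrichment

Over-representation of a hit set within user-supplied annotation sets
(GMT format) is tested against the array background by a one-sided
Fisher's exact test — identical to the hypergeometric upper-tail
probability for the table margins, which the test suite verifies by
direct summation — with BH adjustment across terms. Annotation members are
intersected with the background first; terms with no background member are
skipped. Up- and down-regulated hit sets should be tested separately. No
annotation content is bundled.

## Prediction

Binary classification — old (age at or above 65, the conventional elderly
threshold) versus young, or case versus matched control — by penalized
logistic regression over repeated train/test resampling:

* Per iteration: a stratified split (2/3 train, 1/3 test; stratification
  is a package choice — unstratified splits of a 24-versus-24 cohort
  frequently produce single-class test sets), an elastic-net path
  (`alpha = 0.8`, 100 lambdas) with `lambda.min` chosen by 10-fold
  cross-validated binomial deviance on the training set, probabilities
  thresholded at 0.5 on the held-out third.
* Features are standardized inside each training fit (glmnet's internal
  standardization), so no test-set information leaks.
* The importance index of a feature is the number of iterations (out of
  `n_iter`, default 500) with a nonzero coefficient in the selected model;
  ranking ties are broken lexicographically by feature id.
* Top-k panels (k in 2/5/10/15/20 by default) are refit with a pure ridge
  penalty (`alpha = 0`) under the same resampling, reporting mean
  accuracy, sensitivity, specificity, and the SD of accuracy across
  iterations as the stability measure.
* The positive class (sensitivity orientation) is `old` for the aging task
  and the case group for disease tasks, and is configurable.
* The entire run derives from one seed: per-iteration child seeds are
  drawn once, so reruns are bit-identical and iteration-level failures
  (degenerate CV folds in tiny classes) are redrawn deterministically.

## The synthetic-cohort generator

`synthetic_spec()`/`generate_cohort()` define the conditions under which
every claim above is tested. On the log10 scale each feature gets a
baseline (Normal(3, 0.3) — median fluorescence about 10^3), plus optional
linear age effects, sex effects, disease shifts, step waves (a level shift
for subjects older than a center age — the simplest process with an
unambiguous wave-recovery target), and smooth trajectory templates; the
residual is i.i.d. Gaussian (default SD 0.1). The linear signal is
exponentiated, multiplied by a per-array log-normal scale factor (sdlog
0.2) so quantile normalization has real work to do, and added to a
zero-truncated Normal(500, 50) per-spot background so normexp has real
work to do. Ages are Uniform(19, 79) by default, mirroring a healthy adult
cohort; sex is Bernoulli(0.5) coded female = 0 / male = 1 throughout.

Deliberately not emulated: spatial array artifacts, spot replicates,
antibody cross-reactivity networks, non-uniform age distributions, and
feature-feature correlation beyond what quantile normalization induces.
Consequently, passing recovery tests demonstrates correctness of the
statistical machinery under clean assumptions — not robustness to
structured assay artifacts in real data.

Problem sizes used by the tests and the acceptance script (package
choices): cohorts of 155-300 samples with 180-1,000 features, 10-50
replicate seeds per property, and 100 resampling iterations for the
classifier checks (the methodology is identical at 500; 100 keeps the
default check fast while leaving the reported SD interpretable).

## Known limitations

* Log-scale effect sizes of near-background features are inflated by the
  normexp/log10 interaction (quantified above); comparisons of effect
  *rankings* are unaffected.
* Wave peak ages are identifiable to about the parcel width when effects
  are strong; report the significant-feature sets, not just peak ages.
* Complete linkage at fixed `k` can surrender a cluster to an outlying
  feature; inspect cluster sizes before interpreting mean trajectories.
* The enrichment test is plain Fisher; it does not reproduce
  EASE-adjusted scores or graph-aware GO decorrelation.
* One non-control diagnosis at a time: multi-disease designs are analyzed
  as separate case/control comparisons against matched controls.
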