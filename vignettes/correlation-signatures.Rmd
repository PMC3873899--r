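---
title: "Correlation signatures for drug sensitivity prediction: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation signatures for drug sensitivity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corsens)
```

## The model

`corsens` predicts the *relative* drug sensitivity of samples from their
expression profiles using a two-step correlation scheme.

Given a training panel of cell lines with expression `X` (features ×
samples, logged and median-centered per feature) and drug response `Y`
(drugs × samples, as −log GI50 so larger means more sensitive), training
consists of nothing more than the feature × drug Pearson correlation matrix

$$ r_{fd} = \mathrm{cor}\big(X_{f\cdot},\, Y_{d\cdot}\big) $$

computed across the training lines, pairwise-complete over missing values.
Column $r_{\cdot d}$ is drug *d*'s *sensitivity correlation profile*: the
signed, bounded weight of every feature as a marker of sensitivity
($r>0$) or resistance ($r<0$).

Prediction correlates a test sample's profile $z$ against each drug's
profile: $s_{d} = \mathrm{cor}(r_{\cdot d}, z)$ over the shared features.
Because both steps are Pearson correlations, the score is invariant to
affine rescaling of any feature and of the test profile, which is what
makes projecting signatures across datasets and platforms defensible.
Platform-level prediction matrices are combined by the per-cell unweighted
mean: the scores already share the $[-1,1]$ scale, so no rank
transformation is needed before averaging.

The underlying assumption is that the molecular correlates of drug
response are *widespread* — spread over hundreds of features rather than
concentrated in a few top markers. The method therefore keeps every
feature, weighted by its correlation, instead of selecting a "best"
subset; features without signal contribute weight near zero. The
significance filters (`filter_by_alpha()`) exist to let users test the
opposite regime, and in our simulations with many weak drivers the
restricted runs are indeed slightly worse (see the cutoff experiment
below).

## Evaluation

Per drug, `concordance_index()` implements the tie-aware c-index: over all
unordered sample pairs with distinct observed response, a concordant pair
contributes 1, a discordant pair 0, and a pair tied in the predictions
0.5; pairs tied in the observed values are excluded from both numerator
and denominator, and a drug whose evaluable pairs are all tied is defined
as 0.5. This makes a constant prediction vector score exactly 0.500 —
the chance value — rather than being undefined. `weighted_average_cindex()`
aggregates drugs with configurable nonnegative weights (default 1).
Challenge-style *probabilistic* pair weighting based on replicate
measurement noise is not part of the package's default; the `pair_weight`
hook of `concordance_index()` accepts any `(obs_i, obs_j) -> weight`
function so such variants can be dropped in.

`random_baseline()` gives the distribution-free chance reference: for each
iteration, every drug receives an independent uniform permutation of the
sample order as its prediction, and the aggregate c-index is recorded.
With 2000 iterations the null mean estimates the chance level 0.5 to about
±0.001 at 18 samples × 31 drugs, and the empirical p-value uses the
standard `(#{null ≥ observed} + 1)/(n_iter + 1)` estimator so it is never
exactly zero.

## Normalization

* `log_transform()` — `log_base(value + offset)`, default base 2, offset
  0 (offset 1 recommended for count-scale RNA-seq). Since Pearson
  correlation is affine-invariant per variable, the base cannot change any
  signature or score; it is configurable only so intermediate matrices
  match users' conventions.
* `median_center()` — subtracts each feature's across-sample median
  (non-missing); the training-time centering.
* `robust_zscore()` — (value − median) / SD per feature, the "standard
  deviations from median" scaling applied to tumor cohorts before
  projection. SD uses the n−1 denominator. Zero-variance rows become all
  zeros and are flagged rather than erroring, since constant antibody
  features do occur in small RPPA panels.
* `neglog_response()` — −log of GI50/IC50 concentrations, default base 10
  (molar scale), so that larger transformed values mean more sensitive
  lines. Inputs already on that scale declare it at read time.

Normalization states move forward only (`raw → logged → median_centered`,
`robust_z` from anywhere); double transforms are errors, not warnings,
because a silently re-logged matrix is the most common way this kind of
pipeline goes wrong.

## Numerical conventions and degenerate inputs

* Correlations use pairwise-complete observations; the per-cell sample
  count `n` is recorded and p-values use the t transform
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, two-sided, with
  $p=0$ at $|r|=1$ and `NA` below $n=3$. No multiple-testing correction is
  applied: the filters are raw-P cutoffs by design.
* Cells with fewer than 3 complete pairs or zero variance in either vector
  store $r=0$ and are masked — consistent with the weighted-near-zero
  framing — and are excluded from retained-feature counts.
* Scoring cells with fewer than 3 usable features, or zero variance, are
  missing, not zero.
* Identifier matching (features and samples) is case-folded exact string
  match everywhere; duplicate feature rows collapse by mean at read time
  with a warning.
* Filtered (zeroed) signature cells still participate in scoring as exact
  zeros by default; `drop_zeroed = TRUE` removes them instead, which is
  the variant used for restricted-cutoff comparisons.
* TSV output is written at `%.17g` so round-trips are bit-exact; `NA`
  (or an empty cell) is the only missing marker.

## The simulator and what it does (not) show

`simulate_dataset()` draws from a Gaussian latent-factor model: each
sample carries one latent activity per drug (plus a per-(group, drug)
shift when `n_groups > 1`, giving a two-block, ER±-like structure shared
by cell lines and tumors); each drug plants a driver module whose features
load on its latent; all other features are platform noise; response is
$\beta \cdot \text{latent} + \varepsilon$. Missingness is completely at
random. Driver modules are drawn independently per drug and may overlap;
a feature driving several drugs sums their loadings. All randomness flows
from one `set.seed(seed)` call consumed in a fixed order, so a seed pins
the dataset bit for bit.

Defaults mirror the scale of the motivating study conditions: 35 training
/ 18 test lines, 31 drugs, three platforms (two transcript-level at 2000
features each — a desk-scale stand-in for genome-wide arrays — and a
131-feature protein panel), 100-feature drivers, loading 1, β = 1,
platform noise SD 1, response noise SD 0.25, 5% missing cells, two groups.

The generator reproduces the *statistical structure* the method assumes —
shared latent biology measured by several noisy platforms, widespread
correlated drivers, block structure, MCAR missingness — but not real
data's count distributions, batch effects, feature-feature correlation
beyond the planted modules, or informative missingness. Passing tests
therefore demonstrate correctness and calibration of the machinery, not
clinical performance on real panels.

## Test problem sizes

The package's own experiments (in `tests/testthat/test-acceptance.R`) use:
permutation null at 18 samples × 31 drugs × 2000 iterations; brute-force
oracle checks at 50 features × 10 samples × 4 drugs; parameter recovery at
2000 features / 100-feature drivers / 5 drugs / 35+18 lines over 20
replicates (strong signal: loading 1, β 1, noise SD 0.25 — mean aggregate
c-index ≥ 0.85; null β = 0 — mean within 0.5 ± 0.05); platform averaging
at 3 × 1000 features with independent unit noise over 50 replicates; and
the widespread-weak-signal cutoff comparison at 500 drivers with loading
0.3 over 50 replicates, where the unfiltered run dominates the P<0.05 run,
which dominates the P<0.001 run, on average. These sizes were chosen as the
smallest at which the respective effects are stable across seeds.

## Open design choices, as resolved here

* **Number of drugs in the simulation experiments** is not dictated by the
  panel scale; we use 4–8 drugs in tests (31 in the default config) since
  drug count only averages, rather than changes, the per-drug behavior.
* **Cross-platform feature universes**: each platform trains and scores on
  its full feature set independently before averaging; nothing forces a
  common feature intersection across platforms (projection across
  *datasets* uses `match_features()` explicitly).
* **Retained-feature reporting** accepts an exclusion list of drugs to
  leave out of the across-drug average rather than hard-coding any drug.
* **Drug weights** in the aggregate default to 1 and are configurable;
  the organizers'-style probabilistic pair weights plug in through
  `pair_weight`.
* **Simulated expression is generated on the log scale** (`norm_state =
  "logged"`), so simulated pipelines start at `median_center()`; raw
  concentration-scale inputs go through `log_transform()` first.

## Limitations

Predictions are relative rankings within a sample set; the method offers
no dose calibration. Signature quality degrades with small training
panels (the p-value filters are honest about per-cell `n`, but the
correlations themselves remain noisy), and projection onto tumors assumes
the cell-line-derived correlation structure transfers — an assumption the
package can state but not test. Only expression-like continuous features
are supported: mutation, copy-number and methylation integration are out
of scope.
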