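---
title: "Methods: immune feature modules from stimulation-response cytometry"
author: "stimmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune feature modules from stimulation-response cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its methods: the models and
procedures implemented, the tunable parameters and why their defaults are
what they are, what the synthetic cohort generator does and does not
emulate, and the numerical and design choices made where the field's
practice leaves room.

## 1. From cells to immune features

A stimulation-response experiment produces, per (donor, condition) sample,
a table of cells with one intensity per signaling protein and a cell-type
label (gating is upstream of this package and never simulated or
re-implemented). Features are derived in three steps:

1. **Transform**: `t = arcsinh(x / cofactor)` with cofactor 5, the standard
   variance-stabilising transform for mass-cytometry intensities.
2. **Summarize**: the median of `t` per (cell type, protein) within each
   sample. Medians from cell types with fewer than `min_events` cells
   (default 20) are recorded as missing, not zero: a median of a handful of
   cells is an unstable estimate and silently keeping it would contaminate
   downstream correlations. Missingness propagates — a feature is missing
   for a donor whenever either operand median is missing.
3. **Subtract baseline**: feature = stimulated median − matched
   unstimulated median, for every (protein, cell type, condition) triple
   *including* the unstimulated condition itself (identically zero). That
   convention keeps the pre-threshold feature count equal to the design
   product — 16 × 9 × 15 = 2,160 at the canonical design — with the
   unstimulated block then eliminated by the responsiveness threshold.

**Responsiveness threshold.** Features whose cohort mean is below 0.2
(arcsinh units) are discarded. The boundary is inclusive (mean = 0.2 is
kept); the convention is arbitrary but deterministic and documented. The
default thresholds the *signed* mean, so a feature that responds strongly
downward is also discarded; `use_abs = TRUE` switches to |mean| for
analyses where suppression is of interest. The count of signaling proteins
defaults to 15 (the count that the 2,160 arithmetic requires) and the cell
type count to 9; both are configuration, not constants.

## 2. Module detection

Every retained feature is correlated with every other across donors
(Pearson by default — "R" unqualified in this field means Pearson;
Spearman is an option). Correlations use pairwise-complete donors with the
per-entry donor count recorded; entries supported by fewer than 3 donors,
and all entries of a zero-variance feature, are missing.

Features are clustered by average-linkage agglomeration on distance
`1 − R`. The distance is deliberately *not* `1 − |R|`: anti-correlated
features should not co-cluster, because a module is a block of features
that rise and fall together. Missing correlations enter the distance as 1,
the value an uncorrelated pair would take.

The correlation map is ternarized at `|R| > 0.5` (strict inequality) into
an adjacency matrix with values −1/0/+1. The 0.5 cut is a stringent,
conventional choice that keeps only strongly coordinated pairs.

**Module extraction.** In the original interactive practice, modules are
drawn by eye as contiguous high-correlation blocks on the clustered
heatmap. The package substitutes a deterministic rule with the same
intent: a module is a *maximal* dendrogram clade with at least `min_size`
(4) members whose positive-edge density — the fraction of off-diagonal
member pairs with adjacency +1 — is at least `min_density` (0.5);
maximality means no qualifying clade sits inside another qualifying
clade's ancestor chain. Features in no qualifying clade are `unassigned`.
`min_size = 4` rejects incidental pairs/triplets; `min_density = 0.5`
corresponds to "most member pairs are strongly correlated", which is what
a drawn box encloses visually. Both are exposed in the configuration, and
extraction is invariant to feature input order given the deterministic
tie-handling of the clustering.

Per-module summaries list the proteins, cell types and conditions of the
members and flag the **dominant attribute**: the attribute type (protein
vs cell type vs condition) with the lowest normalized Shannon entropy
across members; exact ties report "none". Within-module versus overall
mean off-diagonal correlation is the headline coherence contrast.

## 3. Module scores

"Normalized" member values are z-scores across donors (the standard choice
when averaging features on different scales; min–max scaling is available
as an option). A donor's module score is the mean of member z-scores,
ignoring missing members; a donor missing every member gets a missing
score, not an imputed one. Unassigned features are scored together as a
pseudo-module, which also forms the 12th member of the test family below
at the canonical 11-module structure. Z-scoring makes scores invariant to
positive affine rescaling of any raw feature, and normalization
parameters are stored so test donors can be scored with training-donor
parameters (no leakage).

## 4. Group comparisons

The statistical primitives are implemented in the package (and
cross-checked against independent references in the test suite):

* **Wilcoxon rank-sum** with midranks; exact by exhaustive enumeration of
  all group splits when both samples have ≤ 10 observations (ties handled
  exactly by enumerating the observed midranks), otherwise a normal
  approximation with tie-corrected variance and continuity correction.
* **Two-sample Kolmogorov–Smirnov**: D = sup |ECDF₁ − ECDF₂| with the
  asymptotic Kolmogorov p-value at effective size n₁n₂/(n₁+n₂) —
  appropriate at the ~40-donors-per-group scale this package targets;
  exact small-sample KS is out of scope.
* **Benjamini–Hochberg** step-up adjustment.

**Module-score comparisons** apply KS per module with BH across the family
(modules + unassigned). **Coordination comparisons** compute per-sex
correlation matrices in the fixed full-cohort clustering order and compare
within-module correlation values between sexes with the rank-sum test,
globally and per module with BH across the family.

**Caveat, and a calibrated alternative.** The coordination test treats
correlation pairs as exchangeable observations. They are not independent:
pairs share donors, and in a latent-factor world all pairs of one module
move together when the latent draw of one group happens to spread wider.
The pair-level Wilcoxon is therefore *descriptive* — it faithfully
reproduces the conventional procedure, and under a planted asymmetry its
direction calls are reliable, but its p-values are anti-conservative under
the null (the package's own null simulations reject in essentially every
cohort at BH 0.05). For calibrated inference the package provides
`bootstrap_correlation_difference()`: the statistic is the difference in
mean within-module correlation, donors (the true sampling units) are
resampled with replacement within each group, and the two-sided p-value
inverts the percentile interval. The bootstrap is quiet under the null and
agrees in direction with the Wilcoxon under planted asymmetries.

## 5. Differential features (SAM)

The unpaired two-class SAM statistic is `d = (x̄₁ − x̄₂)/(s + s₀)` with `s`
the pooled standard error of the difference. The fudge constant `s₀` is
chosen from the percentile grid (0, 5, …, 100%) of the per-feature `s`
values, minimizing the coefficient of variation of the spread of `d`
(median absolute deviation) across 100 `s`-quantile windows — the value
that makes the scale of `d` most independent of `s`.

FDR is estimated by label permutation (exhaustive when the number of label
assignments is ≤ 10,000, else 1,000 random permutations by default): for a
threshold `t`, the estimated FDR is the **average** over permutations of
the count of null |d| values ≥ t, divided by the observed count ≥ t; a
feature's q-value is the minimum FDR over thresholds that call it. The
average (the original SAM convention) rather than the median matters at
extreme thresholds: the median exceedance count at the top observed |d| is
exactly 0 in about half of null datasets, which would yield spurious
q = 0 calls; the mean is ≈ 1 there and calibrates correctly. The median
remains available (`fp_summary = "median"`). Features observed in too few
donors for every possible permutation to leave ≥ 2 usable donors per class
are excluded with a message. Significant features are reported up/down
(sign convention: first factor level minus second) and grouped by protein,
the level at which differential immune features organize.

## 6. Penalized classification

All four classifiers minimize mean logistic loss plus
`λ[α‖β‖₁ + (1−α)Σ_g √p_g ‖β_g‖₂]` (ridge replaces the penalty with
`λ‖β‖₂²/2`), fitted by proximal gradient descent with backtracking line
search. The sparse-group proximal operator is elementwise soft-threshold
then group soft-threshold; group weights are `√p_g`, the standard
group-lasso weighting. The intercept is unpenalized. Columns are
standardized on training data and the parameters re-applied to test data.
Backtracking guarantees a monotone objective; non-convergence within
`max_iter` flags the fit rather than failing silently. Convergence is
certified in the tests by sub-gradient (KKT) residuals and by agreement
with an independent Newton solver at λ = 0.

Tuning is k-fold cross-validation (default k = 10, 3 independent fold
assignments) on mean held-out binomial deviance over a λ grid of 50 points
log-spaced four decades down from λ_max (the smallest λ that zeroes every
coefficient); deviance ties resolve to the larger λ. Unassigned features
enter group penalties as singleton groups by default (configurable to one
pooled group). Evaluation on the held-out donors reports accuracy at
probability 0.5 and AUC via the rank statistic (equivalent to trapezoidal
ROC integration with midrank ties). The canonical cohort split is 50
training / 36 test donors, drawn at random (not stratified, matching the
conventional design; a stratified option exists).

## 7. The synthetic cohort generator

The generator exists so that every downstream stage has a ground truth. On
the arcsinh scale:

* each (cell type, protein) has a fixed baseline median (uniform in
  [0.5, 2]);
* each donor draws one standard-normal latent propensity per protein,
  reused across all of that donor's samples;
* a responsive (protein, cell type, condition) feature's target median is
  `baseline + effect + loading(sex)·z[protein] + shift(sex, protein) + ε`,
  with ε per-(donor, feature) noise;
* single-cell values are Normal around the sample target (the median of a
  Normal is its mean, so targeting is exact), and raw intensities are
  `cofactor·sinh(t)` so the featurizer's transform inverts the
  construction exactly;
* cell-type proportions are Dirichlet around fixed base proportions
  (concentration 300; rarest type 3%, so the default 1,000 cells per
  sample comfortably clears the 20-event floor).

Defaults: 86 donors (43/43 by sex), 16 conditions, 9 cell types, 15
proteins, 1,000 cells per sample; 8 responsive proteins × 4 cell types × 3
stimuli (96 responsive features) with effect 0.8; factor loading 1 and
feature noise SD 0.65, chosen once so the planted within-module pairwise
correlation is ≈ `1/(1 + 0.65²)` ≈ 0.70 — the coherence regime observed in
real cohorts (and squarely inside the 0.6–0.8 band the recovery analyses
assume); cell noise SD 0.6, a typical arcsinh-scale spread.

Sex effects enter through two orthogonal knobs so each downstream result
is independently plantable: `loading_by_sex` scales coordination (per sex,
scalar or per-protein), `mean_shift_by_sex` moves means per protein. The
study conditions used by the acceptance analyses are: loadings 1.5
(female) vs 0.5 (male) in 6 of the 8 planted modules for the coordination
analysis; and a "strong" mean shift of 1.5 arcsinh units (≈ 1.25
within-sex SD) planted male-higher in pSTAT1 and female-higher in pERK1/2
for the differential and classification analyses. The shift magnitude
deserves a note: because all features of a protein share one latent, the
*realized* between-sex difference in a 43 + 43 cohort is the planted shift
plus a cohort-level random offset with SE ≈ 0.22, so a shift must be
comfortably larger than that wobble to be "strong" in every cohort; 1.5
is, 1.0 is not.

**What the generator does not emulate**: spillover, bead normalization,
debarcoding errors, doublets, gating uncertainty (labels are pre-assigned),
non-Normal cell-level distributions, condition-specific latent structure,
or age effects (age is carried but unused). Passing tests therefore
demonstrate that the pipeline recovers the statistical structure it is
designed for — not that real cytometry artifacts are handled; those are
upstream preprocessing concerns.

## 8. Numerical choices and degenerate inputs

* Correlations with < 3 complete donor pairs, and all correlations of
  zero-variance features, are missing; missing distances cluster at 1.
* Zero-variance features are excluded from normalization with a warning;
  an empty module after exclusions is an error naming the module.
* The adjacency boundary is strict (`|R| > cutoff`), the threshold
  boundary inclusive (`mean ≥ 0.2`).
* All-tied Wilcoxon samples give p = 1 with a warning; single-class test
  sets give missing AUC with a warning.
* SAM with a zero-variance feature and s₀ = 0 is an error (infinite d);
  degenerate s distributions fall back to s₀ = median(s) with a warning.
* Every stochastic step (simulation, permutations, splits, folds,
  bootstrap) takes an explicit integer seed and is bit-reproducible.

## 9. Problem sizes used by the test and acceptance analyses

Replicated analyses (module recovery over 20 seeds, null calibration over
20 seeds) run at the full 86-donor design; single-cohort checks use 1,000
cells per sample, while replicated cohorts use 250 cells per sample with
`min_events = 5`. At 250 cells the sample-median noise SD is ≈ 0.05–0.08
arcsinh units — an order of magnitude below the planted donor-level
variation (SD ≈ 1.2) — so the scaled cohorts preserve the statistical
structure the analyses probe. Cross-validation in replicated analyses uses
k = 5 with one fold assignment and a 12-point λ grid; the defaults
(k = 10, 3 repeats, 50 points) remain the recommendation for real
analyses. SAM uses 1,000 permutations in single-cohort analyses and 500 in
the 20-seed null replication.

## 10. Known limitations

* The pair-level Wilcoxon coordination test is anti-conservative (Section
  4); use the donor bootstrap when calibrated p-values matter.
* The module extractor is restricted to dendrogram clades; a
  high-correlation block split across distant clades by a poor linkage
  would be missed. Average linkage on 1 − R makes this rare in practice.
* Thresholding on the signed mean discards strong suppressors by default.
* The asymptotic KS p-value is inaccurate below ~15 donors per group.
* FCS ingestion is delegated to external conversion: the package reads
  per-sample CSV event tables with a cell-type column (gating is out of
  scope), not binary FCS directly.
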