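# stimmod

Module structure of stimulation-response mass-cytometry immune features.

## The problem

Stimulation-response immune profiling measures, for every donor in a cohort,
how strongly each intracellular signaling protein responds in each immune
cell type under each *ex vivo* stimulus. A typical design — whole blood from
86 healthy donors split into 16 aliquots (15 stimuli + an unstimulated
control), 9 gated cell types, 15 phospho-protein readouts per cell — yields
16 × 9 × 15 = 2,160 candidate **immune features** per donor. Across donors,
these features are not independent: a person with a strong pSTAT1 response
in one cell type under one stimulus tends to have strong pSTAT1 responses
everywhere, so features organize into **modules** dominated by signaling
protein. `stimmod` is a tested, reusable implementation of that analysis
for computational immunologists: feature derivation, module detection,
module scoring, sex-stratified coordination analysis, differential-feature
testing, and module-structured penalized classification — plus a synthetic
cohort generator that plants known module and sex-effect structure so every
stage can be validated end to end without access to raw cytometry data.

## The model

**Features.** Per-cell intensities x are transformed as
`t = arcsinh(x / 5)`; per sample the median of t is taken for each
(cell type, protein); the immune feature is the stimulated median minus the
matched unstimulated median, Δ = med_stim − med_unstim. Features whose
cohort mean Δ is below 0.2 are discarded as non-responsive.

**Modules.** Features are correlated across donors (Pearson R, pairwise
complete), hierarchically clustered with average linkage on distance
1 − R, and the correlation map is ternarized at |R| > 0.5 into an adjacency
matrix A ∈ {−1, 0, +1}. Modules are maximal dendrogram clades of ≥ 4
features whose positive-edge density in A is ≥ 0.5. A donor's **module
score** is the mean of the z-normalized member features.

**Inference.** Sex differences in feature levels use SAM's moderated
statistic d = (x̄₁ − x̄₂)/(s + s₀) with a permutation-based FDR;
differences in module scores use the two-sample Kolmogorov–Smirnov test
with Benjamini–Hochberg correction across modules + unassigned;
differences in coordination compare sex-stratified within-module
correlation distributions (Wilcoxon rank-sum, with a calibrated
donor-bootstrap alternative — see the methods vignette for why the
pair-level test is descriptive only).

**Classification.** Donor sex is predicted from features by penalized
logistic regression minimizing

    mean logistic loss + λ [ α‖β‖₁ + (1 − α) Σ_g √p_g ‖β_g‖₂ ]

via proximal gradient descent with backtracking — ridge (λ‖β‖₂²/2), lasso
(α = 1), group lasso (α = 0, groups = modules) and sparse group lasso are
all instances — with λ (and α) tuned by repeated k-fold cross-validation
and performance reported as held-out accuracy and ROC/AUC.

## Worked example

```r
library(stimmod)

res <- simulate_features(sim_config(), seed = 1)  # 86-donor synthetic cohort
print(res$cohort)
#> Synthetic stimulation-response cohort
#>   86 donors (43 female / 43 male), 16 conditions, 9 cell types, 15 proteins
#>   1000 cells per sample; 96 planted responsive features across 8 proteins

print(res$responsive)                             # after the 0.2 threshold
#> Immune feature matrix: 86 donors x 96 features
#>   proteins: 8, cell types: 9, conditions: 15; 6.9% missing

det <- detect_modules(res$responsive)             # correlate-cluster-bin-extract
print(det$modules)
#> 8 modules over 96 features (0 unassigned)
#>   sizes: M1=12, M2=12, M3=12, M4=12, M5=12, M6=12, M7=12, M8=12

w <- within_module_correlation(det$corr, det$modules)
sprintf("within-module mean R = %.2f vs overall %.2f", w$within_mean, w$overall_mean)
#> "within-module mean R = 0.70 vs overall 0.10"

head(module_summary(det$modules, res$responsive$meta)[, c("module", "proteins", "dominant_attribute")], 3)
#>   module proteins dominant_attribute
#> 1     M1   pSTAT5            protein
#> 2     M2     pP38            protein
#> 3     M3   pSTAT6            protein
```

The 2,160-feature enumeration collapses to exactly the 96 planted
responsive features at the 0.2 threshold; the recovered modules coincide
with the planted per-protein modules (adjusted Rand index 1 at this seed),
every module is protein-dominated, and the within-module versus overall
correlation contrast (0.70 vs 0.10) reproduces the qualitative structure of
real stimulation-response cohorts. From here,
`compute_module_scores()` + `compare_module_scores()` test sex differences
in module scores, `sam_permutation_fdr()` finds differential features, and
`fit_all_classifiers()` trains the four penalized models on a 50/36
train/test split. `run_pipeline()` chains all stages and
`write_results()` persists every artifact as CSV/JSON; a thin CLI is
provided at `inst/cli/stimmod`.

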