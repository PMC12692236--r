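---
title: "Mapping determinants of the urinary steroid metabolome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping determinants of the urinary steroid metabolome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

steromap implements a complete analysis chain for studying how clinical,
lifestyle, sociodemographic, genetic and fetal determinants shape the urinary
steroid-hormone (SH) metabolome in pregnancy cohorts. This vignette explains
the statistical model behind each stage, the tunable parameters and their
defaults, what the synthetic-cohort generator does and does not emulate, and
the design choices made where more than one reasonable implementation exists.

## The outcome side: from 50 conjugated metabolites to 89 molecular features

The measurement unit is a panel of 50 phase-II conjugated urinary steroid
metabolites (glucuronides `-G`, monosulfates `-S`, disulfates `-diS`, mixed
sulfoglucoconjugates `-SG`) spanning the androgen, estrogen, progestogen and
corticosteroid branches of steroidogenesis. The built-in registry
(`default_registry()`) annotates each metabolite with its hormone group,
family, conjugation class, molar mass and limit of detection, and defines 39
derived features on top of the individual metabolites:

* **13 sums** — the four family totals plus nine hormone-group totals (DHEA,
  testosterone, cortisol, corticosterone, estradiol, estriol, pregnenolone,
  progesterone, 17-hydroxyprogesterone). Molar concentrations add, so a sum
  is simply the sum of its members in µmol/L. The single-metabolite
  17-hydroxypregnenolone group carries no separate total: a one-member sum
  would duplicate its metabolite column and inflate the outcome count.
* **9 sulfate/glucuronide (S/G) ratios** — sulfate + disulfate members over
  glucuronide members, for the four families and for cortisol, testosterone,
  progesterone, estriol and pregnenolone. A higher value means relatively
  more of the hormone circulates in its sulfo-conjugated (inactive) form.
  Mixed sulfoglucoconjugates belong to neither side and are excluded.
* **17 enzyme-activity indices** — molar product/precursor ratios read off
  the steroidogenesis pathway for named enzymes (aromatase, CYP17
  17α-hydroxylase and 17,20-lyase, 3β-HSD on the progestogen and androgen
  branches, 21-hydroxylase, 11β-HSD1/2, 20α-/20β-reductase,
  5α-/5β-reductase(+3α-HSD), 17β-HSD, 16-hydroxylase, and the
  corticosterone-branch 11β-HSD). These compositions are the package's own
  documented reading of the pathway: the exact product and precursor sets
  behind such indices vary between laboratories, which is why they ship as
  overridable registry data rather than hard-coded formulas.

The total is 50 + 13 + 9 + 17 = 89 outcome features. All registry content —
molar masses (average aglycone mass plus conjugate increments), LODs, and
every derived definition — can be replaced by loading a JSON registry with
`load_registry()`.

## Preprocessing: the fixed order and why

`preprocess_cohort()` applies, in this order:

1. **Left-censored LOD imputation** (`impute_below_lod()`). Below-LOD cells
   are drawn from the left tail of a log-normal fitted to each metabolite by
   censored maximum likelihood, truncated at the LOD. Draws are seeded, so
   the pipeline is reproducible. If every value of a metabolite is censored
   the conventional LOD/√2 constant is used with a warning.
2. **Molar conversion** (`convert_to_molar()`): ng/mL divided by g/mol is
   µmol/L. Ratios and sums are only meaningful in molar units.
3. **Specific-gravity (SG) dilution correction** (`fit_sg_correction()`).
   Urinary concentrations scale with urine concentration. For each
   metabolite we regress `log(conc)` on `log((SG − 1)/(sg_ref − 1))` and
   divide by the dilution factor raised to the fitted exponent; `sg_ref`
   defaults to the cohort median SG. A *fitted* exponent (rather than the
   fixed unit exponent of classical SG standardization) removes the dilution
   trend — post-correction `|r(log conc, SG)|` is below 0.05 in the test
   suite — while leaving metabolite-specific biological variation in place.
4. **Feature derivation** (`derive_features()`). Individual metabolites and
   sums come from the SG-corrected matrix. Ratio features are computed from
   the *uncorrected* molar matrix: a per-subject multiplicative dilution
   factor cancels exactly in a ratio, so correcting first would only inject
   the correction's estimation noise into them. Zero denominators yield
   missing values, never infinities, so the later log2 transform is safe.
5. **Multiples-of-median (MoM) normalization** (`mom_normalize()`). Steroid
   output rises steeply through late gestation, and subjects are sampled at
   different gestational ages. Each feature is divided by the
   gestational-age-specific median predicted by a τ = 0.5 quantile
   regression of the log value on gestational age. The trend is linear: the
   sampling window spans only ~6 weeks, and a median regression with one
   slope is robust and cannot produce a non-positive predicted median after
   back-transformation. MoM is applied to derived ratio features as well as
   individual metabolites by default (`mom_derived = FALSE` turns it off for
   ratios).
6. **log2 transform** — all downstream models work on log2 MoM values, so an
   effect estimate is a log2 fold change.

The QC reproducibility filter (`rsd_filter()`, RSD = sd/mean over replicate
injections, threshold 0.35) operates upstream of all of this, on QC
replicate tables rather than cohort data.

## The determinant side

`prepare_determinants()` fixes the order: missingness filter (subjects with
more than 50% missing determinant data, then columns with more than 50%
missing), correlation pruning, iterative imputation, IQR scaling, dummy
coding.

Pruning removes one member of each continuous pair with |r| > 0.9, dropping
the member with the higher mean absolute correlation to all other continuous
columns (ties by column order) — a deterministic version of standard
redundancy pruning. Only continuous pairs are compared; categorical
determinants are never pruned.

Imputation is missForest-style chained random forests: initialize with
median/mode, re-impute each incomplete column from the others with a random
forest (regression for continuous, classification for categorical), and stop
when the change criterion first rises. Observed cells are never altered, and
the whole procedure is seeded. The forest size (50 trees) trades a small
amount of accuracy for speed; the test suite verifies the imputation beats
marginal (mean) imputation on correlated data.

Continuous determinants are standardized by `(x − median)/IQR`, so
regression coefficients read "log2 feature change per IQR of exposure" —
robust to the skewed, outlier-prone distributions typical of questionnaire
and biomarker exposures. Categorical determinants expand to k−1 indicators
against a reference level (default: the most frequent category). Technical
covariates — season, hospital, COVID-confinement flag — are dummy-coded the
same way but flagged *forced*: they are adjusted for in every model, never
tested, never penalized and never credited with variance shares.

## ExWAS with effective-number-of-tests correction

`fit_exwas()` fits one OLS model per (exposure, feature) pair — feature on
exposure plus forced covariates — exactly like an exposome-wide association
study. With the default schema (54 exposure columns) and 89 features this is
4806 models. Rank-deficient pairs are flagged with missing statistics rather
than aborting the scan.

Because both outcomes and exposures are correlated, Bonferroni over 4806
tests would be needlessly harsh. `ent_thresholds()` estimates the effective
number of tests (ENT) with the Li–Ji eigenvalue estimator: for a correlation
matrix with eigenvalues λ,

ENT = Σ [ I(|λ| ≥ 1) + (|λ| − ⌊|λ|⌋) ].

An identity matrix gives back the full count; a perfectly correlated block
counts once. A separate ENT is computed for each outcome class (individual
metabolites, sums, S/G ratios, enzyme ratios) and one for the dummy-coded
exposure block, and the per-class threshold is
α/(ENT_features × ENT_determinants) with α = 0.05. The estimator choice is
isolated behind `effective_number_of_tests()` so an alternative (e.g.
Galwey or Nyholt) can be substituted without touching the scan. Numerical
note: eigenvalues of degenerate blocks come back a hair under their integer
value, and the floor term would otherwise split an exact eigenvalue of 2
into 1 + 0.999…; a small guard inside the floor prevents this.

## Stability-selected elastic net

Per feature, `fit_enet()` fits an elastic net (α = 0.5, equal L1/L2 mix) of
the log2 feature on all exposures plus forced covariates, with zero penalty
factors on the forced columns. The penalty λ is chosen by 10-fold
cross-validated MSE at its minimum (λ_min); the one-standard-error rule is
available via `lambda_rule = "1se"`. An 80/20 train–test split is used: the
model and its cross-validation live on the training portion and the held-out
MSE is reported as a diagnostic only.

`bootstrap_stability()` then resamples the training subjects with
replacement 100 times, refits the elastic net at the *fixed* λ chosen above,
and records each exposure's selection frequency; exposures selected in at
least 80% of resamples are *stable*. Re-tuning λ inside every bootstrap
would multiply the cost by the CV fold count without changing what the
procedure measures — the sampling stability of the active set at the chosen
regularization — so λ is fixed per feature. Each refit walks a short
descending λ path into the target value, which is how coordinate descent
converges most reliably.

λ_min deliberately over-selects: on pure noise it typically admits one to
three spurious columns. The stability filter is what controls this — in the
packaged benchmarks the false-stable rate is ~2–3% while injected effects of
|β| ≥ 0.5 per IQR are recovered with sensitivity above 0.8 at n = 700.
All per-feature runs derive their seeds from one master seed
(`select_all_features()`), so results do not depend on execution order.

## Variance decomposition (LMG)

For each feature with a non-empty stable set, `fit_final_model()` fits OLS
on the stable exposures plus forced covariates, and `lmg_decomposition()`
attributes the explained variance to determinants by the LMG/Shapley rule:
each determinant's share is its sequential R² increment averaged over all
orderings of the determinants. The dummy columns of one categorical enter
and leave together as a single group, matching how relative-importance
shares are usually reported. With at most 10 groups the decomposition is
exact (all 2^g subset R² values are cached and combined with factorial
weights); above that, orderings are sampled uniformly (default 5000,
seeded), and the sampled mode converges to the exact one within 10⁻³ on the
test fixtures.

Forced covariates sit in every submodel but carry no share: shares sum to
R²_full − R²_covariates. This matches the convention of reporting
determinant contributions net of technical adjustment; in a covariate-free
model the shares sum to the full R² exactly.

## Replication

`replicate_pairs()` re-tests each primary stable (exposure, feature) pair in
the second cohort by OLS with the second cohort's own forced covariates.
Selection is never re-run on the replication cohort. A pair replicates if
its raw p < 0.05 *and* its sign agrees with the primary coefficient (a zero
coefficient counts as inconsistent); no multiplicity correction is applied
at this stage, reflecting the confirmatory, hypothesis-restricted role of
replication. Pairs whose determinant is unavailable in the second cohort are
reported as not testable rather than dropped.

## The synthetic-cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with ground truth attached:

* **Metabolites**: log-normal levels calibrated so that each metabolite hits
  its cohort median and IQR (the calibration tables for both cohorts ship
  with the package, `sh_calibration()`); a within-family Gaussian latent
  factor with correlation 0.25 reproduces the reported family-level
  correlations of roughly 0.2–0.26.
* **Gestational-age trend**: a multiplicative median trend of 5% per week
  around the mean sampling age (34.7 ± 1.5 weeks), rising toward term.
* **Dilution**: specific gravity uniform on (1.005, 1.035); concentrations
  are multiplied by (SG − 1)/(sg_ref − 1), the exact model the SG correction
  assumes with exponent 1.
* **Determinants**: a Table-1-like schema of 47 determinants — 10 phenotype
  scores, 10 SNP allele dosages, 7 three-level and 20 binary categoricals
  with realistic prevalences — expanding to 54 exposure columns, plus forced
  season/hospital/confinement covariates. Missingness is injected MCAR at 5%
  by default.
* **Effects**: a sparse list of (exposure, metabolite, β) triplets applied
  multiplicatively on the log2 scale per IQR of the exposure. Effects on
  individual metabolites propagate naturally into the sums and ratios that
  contain them.
* **LOD censoring**: after conversion to ng/mL, values below the registry
  LOD become missing, to be re-imputed by the pipeline.

`replication_spec()` derives a second-cohort spec: same truth, independent
noise, the replication cohort's own calibration, optional attenuation of
all βs, and a mask of determinants unavailable in the second cohort (whose
effects are dropped, since they are untestable there by construction).

What the generator does **not** emulate: between-family cross-correlations
beyond the latent family factor, measurement batch effects, non-linear or
interaction effects of determinants, informative (non-MCAR) missingness,
genuine pathway stoichiometry linking precursor and product metabolites, and
real LC-MS/MS noise structure. Tests passing on this generator therefore
demonstrate that the estimators recover the structure they assume — not that
the assumptions hold in any particular real cohort.

## Numerical choices and degenerate inputs

* Zero ratio denominators → missing values (degenerate but recoverable);
  non-positive values at the log2 step → an error naming feature and
  subject (a genuine pipeline-order violation).
* SG ≤ 1.000 is physically impossible for urine and raises an error naming
  the subject.
* IQR = 0 in a continuous exposure is an error naming the column: such a
  column (e.g. a rare allele dosage in a small sample) carries no usable
  contrast on the IQR scale.
* Correlation matrices for ENT are computed pairwise-complete, symmetrized,
  and checked for positive semi-definiteness within tolerance.
* The census of random processes — LOD draws, imputation forests, CV folds,
  train/test splits, bootstraps, sampled LMG orderings — all derive from
  explicit seeds; `run_study()` is byte-identical across runs at a fixed
  seed.

## Problem sizes used in the packaged checks

The test suite exercises recovery at the study's own scale where it matters
(n = 700–1000 subjects for selection-recovery and type-I-error checks, 20
replicate cohorts for the stability operating characteristics, 10,000 draws
for the censored-imputation contract) and small fixtures (n ≤ 500, a
three-metabolite toy registry) for the exact oracle comparisons. The
acceptance script runs the full two-cohort study at n = 721 / 500 with
B = 100 bootstrap replications — the default study conditions of the
generator.

## Known limitations

* The derived-feature compositions (sums, S/G ratios, enzyme indices) are a
  documented pathway reading, not a community standard; treat cross-study
  comparisons of the enzyme indices with care and override the registry
  where your laboratory defines them differently.
* The MoM trend is linear in gestational age; for sampling windows much
  wider than the defaults a spline would be preferable.
* LMG shares carry no uncertainty quantification; bootstrap intervals are a
  natural extension but are not implemented.
* The elastic-net stage models each feature independently; multivariate
  outcome structure (e.g. reduced-rank or multi-task penalties) is out of
  scope.
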