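# steromap

Mapping determinants of the urinary steroid-hormone metabolome in pregnancy
cohorts.

Late pregnancy is a period of intense endocrine adaptation: estrogens,
progestogens, androgens and corticosteroids all rise toward term, and the
urinary metabolome — dominated by phase-II conjugates (glucuronides,
sulfates, disulfates, sulfoglucoconjugates) — integrates their production,
enzymatic interconversion and clearance. `steromap` is for epidemiologists
and biostatisticians who have a quantified panel of conjugated urinary
steroid metabolites plus a table of maternal determinants (clinical,
lifestyle, sociodemographic, genetic, fetal) and want to know, reproducibly,
*which determinants shape which parts of steroid metabolism*.

## What it computes

From a 50-metabolite conjugated-steroid panel the package derives **89
steroid-hormone (SH) molecular features**: the 50 individual metabolites, 13
family/hormone-group molar sums, 9 sulfate/glucuronide (S/G) ratios, and 17
enzyme-activity indices (molar product/precursor ratios, e.g. aromatase =
estrogens/androgens). Preprocessing follows standard urinary-metabolomics
practice: reproducibility (RSD ≤ 35%) filtering on QC replicates,
left-censored imputation below the limit of detection, conversion to µmol/L,
specific-gravity dilution correction with metabolite-specific fitted
exponents, multiples-of-median (MoM) normalization for gestational age via
median (τ = 0.5 quantile) regression, and a log2 transform.

Determinant mapping then proceeds in four stages:

1. **ExWAS** — one OLS fit per (exposure, feature) pair, adjusted for forced
   technical covariates, with multiple testing controlled per outcome class
   by the effective number of tests (Li–Ji eigenvalue estimator):
   `p_ENT = α / (ENT_features × ENT_determinants)`.
2. **Stability-selected elastic net** — per feature, an α = 0.5 elastic net
   with 10-fold cross-validated λ and unpenalized forced covariates;
   exposures selected in ≥ 80% of 100 bootstrap refits are *stable*.
3. **LMG variance decomposition** — the final OLS model on the stable set is
   decomposed into per-determinant R² shares by averaging sequential R²
   increments over predictor orderings (the Shapley value of the R² game),
   with a categorical's dummies treated as one group.
4. **Replication** — primary stable pairs are re-tested in a second cohort
   with its own covariates; a pair replicates at raw p < 0.05 with a
   consistent sign.

A calibrated synthetic two-cohort generator (`generate_cohort()`,
`replication_spec()`) emulates the assumed data structure — log-normal
metabolites matching published median/IQR tables, family correlation blocks,
gestational-age trends, specific-gravity dilution, LOD censoring, a
47-determinant mixed schema expanding to 54 exposure columns, sparse known
effects — so every stage can be benchmarked against ground truth.

## Worked example

```r
library(steromap)

reg <- default_registry()
reg
#> <sh_registry builtin-1.0>
#>   metabolites: 50
#>   derived: 39 (13 sums, 9 S/G ratios, 17 enzyme ratios)

# a synthetic cohort with two known determinant effects
truth <- tibble::tibble(
  exposure_id = c("bmi_t3", "age"),
  feature_id  = c("F-G", "Andros-G"),   # cortisol-G up with BMI, androsterone-G down with age
  beta        = c(0.8, -0.8))           # log2 change per IQR of the exposure
spec  <- cohort_spec(n_subjects = 400, effects = truth, seed = 2024)
gen   <- generate_cohort(spec)
study <- run_study(gen, B = 50, seed = 1)

study$ent$groups
#>   feature_class     m   ent     p_ent
#> 1 individual       50    41 0.0000226
#> 2 sum              13     9 0.000103
#> 3 sg_ratio          9     8 0.000116
#> 4 enzyme_ratio     17    15 0.0000617

sel <- study$selection$selection
sel[sel$stable & sel$determinant %in% c("bmi_t3", "age"),
    c("feature", "exposure", "frequency", "coef_sign")]
#>    feature                exposure frequency coef_sign
#>  1 F-G                    bmi_t3        1            1
#>  3 Andros-G               age           1           -1
#>  4 total_androgens        age           1           -1
#>  6 sg_androgens           age           1            1
#>  8 enz_aromatase          age           1            1
#> 12 enz_5a_reductase_3ahsd age           1           -1
#>  ...
```

Both injected effects are recovered at selection frequency 1.0 with the
correct sign — and, because a change in an individual metabolite propagates
into every sum and ratio containing it, the age effect on
androsterone-glucuronide also surfaces in total androgens, the androgen S/G
ratio and the 5α-reductase index, with coherent signs. The variance
decomposition attributes the corresponding R²:

```r
sv <- study$variance$table
head(sv[order(-sv$share), c("feature", "group", "share", "total_r2")], 3)
#>   feature                group  share total_r2
#> 1 F-G                    bmi_t3 0.296    0.336
#> 2 Andros-G               age    0.284    0.294
#> 3 enz_5a_reductase_3ahsd age    0.229    0.240
```

On real data, replace the generator output with `read_cohort()` (subjects ×
metabolites CSV/TSV with `subject_id`, `specific_gravity`,
`gestational_age_weeks`) and `sh_determinants()` (determinant table plus a
column schema), then call the same `run_study()`.

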