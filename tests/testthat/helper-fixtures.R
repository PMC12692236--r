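# Shared fixtures, built once per run and cached.

.fixtures <- new.env(parent = emptyenv())

# A small fully processed cohort: 150 subjects, default schema/calibration,
# no injected effects. Used wherever a realistic feature/exposure design is
# needed without caring about effect recovery.
small_prepared <- function() {
  if (!exists("small", .fixtures)) {
    spec <- cohort_spec(n_subjects = 150, missing_rate = 0.02, seed = 101)
    g <- generate_cohort(spec)
    pp <- suppressWarnings(preprocess_cohort(g$cohort, spec$registry, seed = 1))
    dp <- prepare_determinants(g$determinants, seed = 2)
    feats <- steromap:::align_subjects(pp$features, dp$exposures)
    expo <- steromap:::align_subjects(dp$exposures, feats)
    assign("small", list(spec = spec, gen = g, prep = pp, feats = feats, expo = expo), .fixtures)
  }
  get("small", .fixtures)
}

# Restrict a feature tibble to a subset of feature columns, keeping class
# metadata intact.
subset_features <- function(features, cols) {
  out <- features[, c("subject_id", cols)]
  attr(out, "feature_class") <- feature_classes(features)[cols]
  class(out) <- class(features)
  out
}

# Tiny hand-built registry: three metabolites of one hormone group with one
# sum, one S/G ratio and one enzyme ratio.
toy_registry <- function() {
  met <- tibble::tibble(
    id = c("X-G", "X-S", "Y-S"),
    full_name = c("X glucuronide", "X sulfate", "Y sulfate"),
    hormone_group = c("X", "X", "Y"),
    family = c("androgen", "androgen", "androgen"),
    conjugation = c("glucuronide", "sulfate", "sulfate"),
    molar_mass = c(400, 380, 390),
    lod = c(1, 1, 1)
  )
  der <- tibble::tibble(
    id = c("total_x", "sg_x", "enz_y_from_x"),
    feature_class = c("sum", "sg_ratio", "enzyme_ratio"),
    label = c("total X", "S/G X", "Y/X conversion"),
    numerator_ids = list(c("X-G", "X-S"), "X-S", "Y-S"),
    denominator_ids = list(character(0), "X-G", c("X-G", "X-S"))
  )
  reg <- list(metabolites = met, derived = der, version = "toy")
  class(reg) <- "sh_registry"
  steromap:::validate_registry(reg)
  reg
}

toy_cohort <- function(values, unit = "umol_l") {
  n <- nrow(values)
  sh_cohort(
    tibble::tibble(
      subject_id = sprintf("S%02d", seq_len(n)),
      specific_gravity = rep(1.02, n),
      gestational_age_weeks = rep(34, n),
      values
    ),
    unit = unit, correction = "raw"
  )
}
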