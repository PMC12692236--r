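# Synthetic paired-cohort generator. Emulates the statistical structure
# the analysis assumes: log-normal metabolite concentrations calibrated to
# the cohort medians/IQRs with a family-block correlation, a gestational-
# age median trend, per-subject specific-gravity dilution, LOD censoring,
# a Table-1-like determinant schema (47 determinants expanding to 54
# exposure columns) with MCAR missingness, and sparse known
# determinant -> metabolite effects on the log2 scale carried as ground
# truth for recovery benchmarks.

#' Default determinant schema
#'
#' A Table-1-like mixed schema: 20 continuous determinants (10 phenotype
#' scores plus 10 SNP allele dosages), 7 three-level and 20 binary
#' categorical determinants (47 in total, expanding to 54 exposure columns
#' after dummy coding), plus forced technical covariates (season,
#' hospital, COVID confinement). Generation parameters (means/SDs,
#' category prevalences) are carried in the `gen` list-column.
#'
#' @return Schema tibble usable both for generation and as the
#'   [sh_determinants()] schema.
#' @export
default_determinant_schema <- function() {
  cont <- function(id, family, mean, sd) {
    tibble::tibble(
      id = id, type = "continuous", family = family, forced = FALSE,
      levels = list(NULL), reference = NA_character_,
      gen = list(list(mean = mean, sd = sd))
    )
  }
  snp <- function(id, maf) {
    tibble::tibble(
      id = id, type = "continuous", family = "genetic", forced = FALSE,
      levels = list(NULL), reference = NA_character_,
      gen = list(list(maf = maf))
    )
  }
  cat3 <- function(id, family, levels, prob, ref) {
    tibble::tibble(
      id = id, type = "categorical", family = family, forced = FALSE,
      levels = list(levels), reference = ref, gen = list(list(prob = prob))
    )
  }
  bin <- function(id, family, prev) {
    tibble::tibble(
      id = id, type = "categorical", family = family, forced = FALSE,
      levels = list(c("no", "yes")), reference = "no",
      gen = list(list(prob = c(1 - prev, prev)))
    )
  }
  tech <- function(id, levels, prob, ref) {
    tibble::tibble(
      id = id, type = "categorical", family = "technical", forced = TRUE,
      levels = list(levels), reference = ref, gen = list(list(prob = prob))
    )
  }
  dplyr::bind_rows(
    cont("age", "sociodemographic", 34.4, 4.4),
    cont("bmi_t3", "clinical", 26.5, 3.6),
    cont("weight_gain", "clinical", 10, 4),
    cont("amed_score", "lifestyle", 3.9, 1.8),
    cont("fat_intake", "lifestyle", 35, 6),
    cont("psqi", "lifestyle", 6, 3),
    cont("pss_stress", "mental_health", 14, 6),
    cont("epds_depression", "mental_health", 6, 4),
    cont("fetal_weight_20w", "fetal", 350, 50),
    cont("fetal_weight_t3", "fetal", 2200, 300),
    snp("snp_rs2300701", 0.40), snp("snp_rs806645", 0.35),
    snp("snp_rs1056836", 0.45), snp("snp_rs1264459", 0.30),
    snp("snp_rs1937863", 0.35), snp("snp_rs743572", 0.40),
    snp("snp_rs10046", 0.45), snp("snp_rs28757184", 0.25),
    snp("snp_rs700518", 0.45), snp("snp_rs6493497", 0.30),
    cat3("origin", "sociodemographic", c("spain", "latin_america", "other"), c(0.69, 0.23, 0.08), "spain"),
    cat3("education", "sociodemographic", c("primary", "secondary", "university"), c(0.04, 0.24, 0.72), "university"),
    cat3("parity", "clinical", c("nulliparous", "primiparous", "multiparous"), c(0.61, 0.32, 0.07), "nulliparous"),
    cat3("alcohol", "lifestyle", c("none", "low", "high"), c(0.95, 0.03, 0.02), "none"),
    cat3("smoking", "lifestyle", c("none", "light", "heavy"), c(0.96, 0.02, 0.02), "none"),
    cat3("contraception", "clinical", c("none", "non_hormonal", "hormonal"), c(0.13, 0.67, 0.20), "non_hormonal"),
    cat3("sleep_duration", "lifestyle", c("short", "mid", "long"), c(0.21, 0.64, 0.15), "mid"),
    bin("mvpa_over_150min", "lifestyle", 0.22),
    bin("folic_acid", "lifestyle", 0.74),
    bin("fetal_sex_female", "fetal", 0.49),
    bin("pcos", "clinical", 0.05),
    bin("preeclampsia_mild", "clinical", 0.03),
    bin("diabetes_type1", "clinical", 0.02),
    bin("gestational_diabetes", "clinical", 0.06),
    bin("hypertension", "clinical", 0.04),
    bin("abnormal_amniotic_fluid", "clinical", 0.03),
    bin("progesterone_medication", "clinical", 0.05),
    bin("corticosteroid_medication", "clinical", 0.03),
    bin("fertility_treatment", "clinical", 0.08),
    bin("thyroid_medication", "clinical", 0.05),
    bin("iron_supplement", "lifestyle", 0.30),
    bin("multivitamin_use", "lifestyle", 0.50),
    bin("passive_smoking", "lifestyle", 0.15),
    bin("employed", "sociodemographic", 0.75),
    bin("previous_miscarriage", "clinical", 0.15),
    bin("gestational_anemia", "clinical", 0.10),
    bin("urinary_tract_infection", "clinical", 0.08),
    tech("season", c("autumn", "spring", "summer", "winter"), c(0.25, 0.24, 0.30, 0.21), "summer"),
    tech("hospital", c("hospital_a", "hospital_b", "hospital_c"), c(0.40, 0.35, 0.25), "hospital_a"),
    tech("confinement", c("no", "yes"), c(0.73, 0.27), "no")
  )
}

#' Specify a synthetic cohort
#'
#' @param n_subjects Number of subjects (>= 1); default 721, the primary
#'   cohort size.
#' @param ga_mean,ga_sd Gestational age at sampling, weeks (default
#'   34.7 / 1.5).
#' @param sg_range Specific-gravity sampling interval, within
#'   (1.000, 1.060); default c(1.005, 1.035).
#' @param calibration Tibble `id`, `median`, `iqr` (umol/L); default the
#'   primary-cohort calibration [sh_calibration()].
#' @param determinant_schema Schema tibble; default
#'   [default_determinant_schema()].
#' @param missing_rate MCAR missingness fraction injected into non-forced
#'   determinants, in [0, 0.5); default 0.05.
#' @param effects Tibble of ground-truth effects: `exposure_id` (an
#'   exposure column name), `feature_id` (a metabolite id), `beta` (log2
#'   change per IQR of the exposure, or per indicator level).
#' @param family_cor Within-family latent correlation of log metabolite
#'   levels (default 0.25, matching the reported family correlations of
#'   roughly 0.2-0.26).
#' @param ga_trend Per-week multiplicative median trend on the log scale
#'   (default 0.05: levels rise toward term).
#' @param registry A `sh_registry` (molar masses and LODs).
#' @param seed Integer seed.
#' @return A validated `sh_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 721, ga_mean = 34.7, ga_sd = 1.5,
                        sg_range = c(1.005, 1.035),
                        calibration = sh_calibration("bisc"),
                        determinant_schema = default_determinant_schema(),
                        missing_rate = 0.05,
                        effects = NULL,
                        family_cor = 0.25, ga_trend = 0.05,
                        registry = default_registry(), seed = 1L) {
  stopifnot(n_subjects >= 1)
  if (!(sg_range[1] > 1.000 && sg_range[2] < 1.060 && sg_range[1] < sg_range[2])) {
    stop("sg_range must lie within (1.000, 1.060)", call. = FALSE)
  }
  if (!(missing_rate >= 0 && missing_rate < 0.5)) stop("missing_rate must be in [0, 0.5)", call. = FALSE)
  if (is.null(effects)) {
    effects <- tibble::tibble(exposure_id = character(0), feature_id = character(0), beta = numeric(0))
  }
  unknown <- setdiff(effects$feature_id, registry$metabolites$id)
  if (length(unknown)) stop("effect feature_id(s) not in registry: ", paste(unknown, collapse = ", "), call. = FALSE)
  miss_cal <- setdiff(registry$metabolites$id, calibration$id)
  if (length(miss_cal)) stop("calibration lacks metabolite(s): ", paste(miss_cal, collapse = ", "), call. = FALSE)
  spec <- list(
    n_subjects = as.integer(n_subjects), ga_mean = ga_mean, ga_sd = ga_sd,
    sg_range = sg_range, calibration = calibration,
    determinant_schema = determinant_schema, missing_rate = missing_rate,
    effects = tibble::as_tibble(effects), family_cor = family_cor,
    ga_trend = ga_trend, registry = registry, seed = as.integer(seed)
  )
  class(spec) <- "sh_cohort_spec"
  spec
}

generate_determinant_data <- function(schema, n) {
  out <- list(subject_id = sprintf("S%04d", seq_len(n)))
  for (k in seq_len(nrow(schema))) {
    id <- schema$id[k]
    gen <- schema$gen[[k]]
    if (schema$type[k] == "continuous") {
      out[[id]] <- if (!is.null(gen$maf)) {
        stats::rbinom(n, 2, gen$maf)
      } else {
        stats::rnorm(n, gen$mean, gen$sd)
      }
    } else {
      lev <- schema$levels[[k]]
      out[[id]] <- sample(lev, n, replace = TRUE, prob = gen$prob)
    }
  }
  tibble::as_tibble(out)
}

# complete (pre-missingness) dummy design used to inject effects
effect_design <- function(det_complete) {
  dummy_code(det_complete, scale_continuous = TRUE)
}

#' Generate a synthetic cohort
#'
#' Draws determinants from the schema, latent log-normal metabolite levels
#' calibrated to the target medians/IQRs with a within-family correlation
#' block, applies the ground-truth determinant effects on the log2 scale,
#' a gestational-age median trend and per-subject specific-gravity
#' dilution, converts to ng/mL, censors values below the registry LOD to
#' `NA`, and injects MCAR missingness into the determinants. Identical
#' spec and seed give identical output.
#'
#' @param spec A `sh_cohort_spec`.
#' @return List with `determinants` (a `sh_determinants`, with
#'   missingness), `cohort` (a raw ng/mL `sh_cohort` with LOD-censored
#'   entries as `NA`), `truth` (the effect tibble) and `exposures_true`
#'   (the complete pre-missingness exposure design the effects used).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sh_cohort_spec"))
  reg <- spec$registry
  met <- reg$metabolites
  n <- spec$n_subjects
  withr::with_seed(spec$seed, {
    schema <- spec$determinant_schema
    det_data <- generate_determinant_data(schema, n)
    det_complete <- sh_determinants(det_data, schema)
    X <- effect_design(det_complete)

    ga <- stats::rnorm(n, spec$ga_mean, spec$ga_sd)
    sg <- stats::runif(n, spec$sg_range[1], spec$sg_range[2])
    sg_ref <- mean(spec$sg_range)

    cal <- spec$calibration[match(met$id, spec$calibration$id), ]
    sdlog <- asinh(cal$iqr / (2 * cal$median)) / stats::qnorm(0.75)
    z_fam <- matrix(stats::rnorm(n * 4), n, 4,
      dimnames = list(NULL, c("androgen", "estrogen", "progestogen", "corticosteroid"))
    )
    conc <- matrix(NA_real_, n, nrow(met), dimnames = list(NULL, met$id))
    rho <- spec$family_cor
    for (i in seq_len(nrow(met))) {
      z <- sqrt(rho) * z_fam[, met$family[i]] + sqrt(1 - rho) * stats::rnorm(n)
      lg <- log(cal$median[i]) + sdlog[i] * z + spec$ga_trend * (ga - spec$ga_mean)
      conc[, i] <- exp(lg)
    }
    # ground-truth effects, multiplicative on the log2 scale
    if (nrow(spec$effects)) {
      for (e in seq_len(nrow(spec$effects))) {
        xcol <- spec$effects$exposure_id[e]
        if (!xcol %in% names(X)) stop("effect exposure_id not an exposure column: ", xcol, call. = FALSE)
        conc[, spec$effects$feature_id[e]] <-
          conc[, spec$effects$feature_id[e]] * 2^(spec$effects$beta[e] * X[[xcol]])
      }
    }
    dilution <- (sg - 1) / (sg_ref - 1)
    conc <- conc * dilution
    # to ng/mL, then LOD censoring
    conc <- sweep(conc, 2, met$molar_mass, `*`)
    for (i in seq_len(nrow(met))) {
      conc[conc[, i] < met$lod[i], i] <- NA_real_
    }
    # MCAR missingness on non-forced determinants
    det_miss <- det_complete$data
    if (spec$missing_rate > 0) {
      for (id in schema$id[!schema$forced]) {
        hit <- stats::runif(n) < spec$missing_rate
        det_miss[[id]][hit] <- NA
      }
    }
  })
  cohort <- sh_cohort(
    tibble::tibble(
      subject_id = det_data$subject_id,
      specific_gravity = sg,
      gestational_age_weeks = ga,
      tibble::as_tibble(conc)
    ),
    unit = "ng_ml", correction = "raw"
  )
  dets <- sh_determinants(det_miss, schema)
  list(determinants = dets, cohort = cohort, truth = spec$effects, exposures_true = X)
}

#' Derive a replication-cohort spec from a primary spec
#'
#' Same ground truth with independent noise, the replication-cohort
#' calibration, optionally attenuated effect sizes, and a schema mask for
#' determinants unavailable in the second cohort.
#'
#' @param spec Primary `sh_cohort_spec`.
#' @param n_subjects Replication sample size (default 500).
#' @param calibration Metabolite calibration (default the replication
#'   cohort's, `sh_calibration("inma")`).
#' @param attenuation Multiplier on all effect betas (default 1).
#' @param drop_determinants Determinant ids absent from the replication
#'   cohort (e.g. SNPs, mental health); removed from the schema.
#' @param seed Seed for the independent noise.
#' @return A `sh_cohort_spec`.
#' @export
replication_spec <- function(spec, n_subjects = 500,
                             calibration = sh_calibration("inma"),
                             attenuation = 1, drop_determinants = character(0),
                             seed = spec$seed + 1L) {
  schema <- spec$determinant_schema
  schema <- schema[!schema$id %in% drop_determinants, , drop = FALSE]
  eff <- spec$effects
  if (nrow(eff) && length(drop_determinants)) {
    dropped <- vapply(eff$exposure_id, function(x) {
      any(x == drop_determinants | startsWith(x, paste0(drop_determinants, "_")))
    }, logical(1))
    eff <- eff[!dropped, , drop = FALSE]
  }
  eff$beta <- eff$beta * attenuation
  cohort_spec(
    n_subjects = n_subjects, ga_mean = spec$ga_mean, ga_sd = spec$ga_sd,
    sg_range = spec$sg_range, calibration = calibration,
    determinant_schema = schema, missing_rate = spec$missing_rate,
    effects = eff, family_cor = spec$family_cor, ga_trend = spec$ga_trend,
    registry = spec$registry, seed = seed
  )
}

#' Generate a QC replicate panel with known reproducibility
#'
#' Builds a replicate table in which `n_bad` features have a construction
#' RSD above the 0.35 exclusion threshold (0.6 by default) and the rest
#' are below it (0.15): replicate draws are standardized so the sample
#' RSD equals the target exactly.
#'
#' @param n_features Total features.
#' @param n_bad Features built irreproducible (`<= n_features`).
#' @param n_replicates Replicates per feature (>= 2).
#' @param seed Integer seed.
#' @param rsd_bad,rsd_good Construction RSDs (defaults 0.6 / 0.15).
#' @return Matrix of `n_replicates` x `n_features` QC values.
#' @export
generate_qc_panel <- function(n_features, n_bad, n_replicates = 10, seed = 1L,
                              rsd_bad = 0.6, rsd_good = 0.15) {
  stopifnot(n_bad <= n_features, n_bad >= 0)
  if (n_replicates < 2) stop("need at least 2 replicates", call. = FALSE)
  target <- c(rep(rsd_bad, n_bad), rep(rsd_good, n_features - n_bad))
  withr::with_seed(seed, {
    m <- vapply(seq_len(n_features), function(j) {
      mu <- stats::runif(1, 0.5, 5)
      z <- stats::rnorm(n_replicates)
      z <- (z - mean(z)) / stats::sd(z)
      mu * (1 + target[j] * z)
    }, numeric(n_replicates))
  })
  colnames(m) <- sprintf("feat_%02d", seq_len(n_features))
  m
}
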