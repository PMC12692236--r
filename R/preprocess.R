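# Metabolite-side preprocessing. The pipeline order is fixed:
# LOD-impute (ng/mL) -> molar conversion -> SG correction -> feature
# derivation (ratios from the pre-SG matrix) -> MoM gestational-age
# normalization -> log2.

#' Reproducibility (RSD) filter on QC replicates
#'
#' Computes the relative standard deviation (sample sd / mean) of each
#' feature across quality-control replicate injections and flags features
#' exceeding the reproducibility threshold for exclusion.
#'
#' @param qc_replicates Numeric matrix or data frame, replicates in rows,
#'   features in columns; at least 2 replicates.
#' @param threshold RSD threshold above which a feature is excluded
#'   (default 0.35, i.e. 35%).
#' @return A `sh_qc` list with per-feature `rsd`, logical `retained`
#'   (`rsd <= threshold`), and `threshold`. A non-positive replicate mean
#'   flags the feature as not retained with infinite RSD.
#' @export
rsd_filter <- function(qc_replicates, threshold = 0.35) {
  m <- as.matrix(qc_replicates)
  storage.mode(m) <- "double"
  if (nrow(m) < 2) stop("need at least 2 QC replicates per feature", call. = FALSE)
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  rsd <- ifelse(mu > 0, sdv / mu, Inf)
  names(rsd) <- colnames(m)
  res <- list(rsd = rsd, retained = rsd <= threshold, threshold = threshold)
  class(res) <- "sh_qc"
  res
}

# censored log-normal MLE: observed values contribute the density, censored
# entries contribute the left-tail mass below their LOD
fit_lognormal_censored <- function(observed, n_censored, lod) {
  lx <- log(observed)
  start <- c(mean(lx), max(stats::sd(lx), 1e-3))
  nll <- function(p) {
    mu <- p[1]
    sigma <- exp(p[2])
    -(sum(stats::dlnorm(observed, mu, sigma, log = TRUE)) +
      n_censored * stats::plnorm(lod, mu, sigma, log.p = TRUE))
  }
  fit <- stats::optim(c(start[1], log(start[2])), nll, method = "Nelder-Mead")
  c(meanlog = fit$par[1], sdlog = exp(fit$par[2]))
}

#' Impute values below the limit of detection
#'
#' Censored entries (`NA`) are replaced by random draws from the left tail
#' (below `lod`) of a log-normal distribution fitted to the data by
#' censored maximum likelihood. Observed entries are never altered; the
#' result is deterministic given `seed`.
#'
#' @param values Numeric vector for one metabolite; `NA` marks a
#'   below-LOD measurement.
#' @param lod Limit of detection, same unit as `values`.
#' @param seed Integer seed.
#' @return `values` with censored entries replaced by draws in `(0, lod)`.
#'   If every value is censored the constant `lod/sqrt(2)` is used and a
#'   warning is raised.
#' @export
impute_below_lod <- function(values, lod, seed = 1L) {
  stopifnot(lod >= 0)
  cens <- which(is.na(values))
  if (!length(cens)) {
    return(values)
  }
  obs <- values[!is.na(values)]
  if (!length(obs)) {
    warning("all values censored; falling back to lod/sqrt(2)", call. = FALSE)
    values[cens] <- lod / sqrt(2)
    return(values)
  }
  par <- fit_lognormal_censored(obs, length(cens), lod)
  p_lod <- stats::plnorm(lod, par["meanlog"], par["sdlog"])
  p_lod <- max(p_lod, 1e-12) # guard: tail mass can underflow for high means
  withr::with_seed(seed, {
    u <- stats::runif(length(cens), 0, p_lod)
    values[cens] <- pmin(stats::qlnorm(u, par["meanlog"], par["sdlog"]), lod * (1 - 1e-9))
  })
  values
}

impute_cohort_lod <- function(cohort, registry, seed = 1L) {
  if (cohort_unit(cohort) != "ng_ml") stop("LOD imputation expects ng/mL concentrations", call. = FALSE)
  met <- registry$metabolites
  for (k in seq_len(nrow(met))) {
    id <- met$id[k]
    if (!id %in% names(cohort)) next
    cohort[[id]] <- impute_below_lod(cohort[[id]], met$lod[k], seed = seed + k)
  }
  cohort
}

#' Convert mass to molar concentration
#'
#' ng/mL divided by the molar mass in g/mol is numerically equal to
#' nmol/mL = umol/L.
#'
#' @param conc_ng_ml Non-negative concentration(s) in ng/mL.
#' @param molar_mass_g_mol Molar mass in g/mol (> 0).
#' @return Concentration(s) in umol/L.
#' @export
convert_to_molar <- function(conc_ng_ml, molar_mass_g_mol) {
  stopifnot(molar_mass_g_mol > 0)
  if (any(conc_ng_ml < 0, na.rm = TRUE)) stop("negative concentration", call. = FALSE)
  conc_ng_ml / molar_mass_g_mol
}

convert_cohort_to_molar <- function(cohort, registry) {
  if (cohort_unit(cohort) != "ng_ml") stop("cohort already in molar units", call. = FALSE)
  met <- registry$metabolites
  for (k in seq_len(nrow(met))) {
    id <- met$id[k]
    if (!id %in% names(cohort)) next
    cohort[[id]] <- convert_to_molar(cohort[[id]], met$molar_mass[k])
  }
  attr(cohort, "unit") <- "umol_l"
  cohort
}

#' Fit the specific-gravity dilution correction
#'
#' Urinary concentrations scale with urine concentration/dilution. For each
#' metabolite a dilution exponent `b` is fitted by regressing `log(conc)`
#' on `log((SG - 1)/(sg_ref - 1))`; the corrected concentration is
#' `conc / ((SG - 1)/(sg_ref - 1))^b`. A fitted (rather than fixed unit)
#' exponent removes the SG dependence while preserving metabolite-specific
#' biological variation.
#'
#' @param cohort A `sh_cohort` in umol/L with `specific_gravity` > 1.000.
#' @param sg_ref Reference specific gravity; default the cohort median SG.
#' @return A `sh_sg_model`: per-metabolite slopes and `sg_ref`.
#' @export
fit_sg_correction <- function(cohort, sg_ref = NULL) {
  sg <- cohort$specific_gravity
  bad <- which(sg <= 1.000)
  if (length(bad)) {
    stop("specific gravity <= 1.000 for subject ", cohort$subject_id[bad[1]], call. = FALSE)
  }
  sg_ref <- sg_ref %||% stats::median(sg)
  ld <- log((sg - 1) / (sg_ref - 1))
  cols <- metabolite_cols(cohort)
  slope <- vapply(cols, function(j) {
    y <- log(pmax(cohort[[j]], .Machine$double.eps))
    ok <- is.finite(y) & is.finite(ld)
    unname(stats::coef(stats::lm.fit(cbind(1, ld[ok]), y[ok]))[2])
  }, numeric(1))
  res <- list(slope = slope, sg_ref = sg_ref)
  class(res) <- "sh_sg_model"
  res
}

#' Apply a fitted specific-gravity correction
#'
#' @param cohort A `sh_cohort` in umol/L, raw correction state.
#' @param model A `sh_sg_model` from [fit_sg_correction()].
#' @return The cohort with corrected concentrations and correction state
#'   `"sg"`.
#' @export
apply_sg_correction <- function(cohort, model) {
  stopifnot(inherits(model, "sh_sg_model"))
  sg <- cohort$specific_gravity
  if (any(sg <= 1.000)) stop("specific gravity <= 1.000", call. = FALSE)
  d <- (sg - 1) / (model$sg_ref - 1)
  for (j in intersect(names(model$slope), names(cohort))) {
    cohort[[j]] <- cohort[[j]] / d^model$slope[[j]]
  }
  attr(cohort, "correction") <- "sg"
  cohort
}

#' Fit gestational-age median trends for MoM normalization
#'
#' For each column a tau = 0.5 (median) quantile regression of the log
#' value on gestational age is fitted; the predicted median, back on the
#' original scale, is the denominator of the multiples-of-median (MoM)
#' transform. A linear trend is used: the sampling window spans only a few
#' weeks.
#'
#' @param x Matrix/tibble of strictly positive values (metabolites or
#'   derived features), or a `sh_features` tibble.
#' @param gestational_age Gestational age in weeks, one value per row.
#' @return A `sh_mom_model` with per-column intercept/slope and the fitted
#'   age range.
#' @export
fit_mom_model <- function(x, gestational_age) {
  m <- if (inherits(x, "sh_features")) feature_matrix(x) else as.matrix(x)
  stopifnot(nrow(m) == length(gestational_age))
  coefs <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    ok <- is.finite(v) & v > 0 & is.finite(gestational_age)
    if (sum(ok) < 3) stop("too few positive values to fit MoM trend for column ", colnames(m)[j], call. = FALSE)
    fit <- suppressWarnings(
      quantreg::rq(log(v[ok]) ~ gestational_age[ok], tau = 0.5, method = "br")
    )
    stats::coef(fit)
  }, numeric(2))
  res <- list(
    intercept = stats::setNames(coefs[1, ], colnames(m)),
    slope = stats::setNames(coefs[2, ], colnames(m)),
    ga_range = range(gestational_age, finite = TRUE)
  )
  class(res) <- "sh_mom_model"
  res
}

#' Multiples-of-median (MoM) normalization
#'
#' Divides each observation by the gestational-age-specific median
#' predicted by the fitted quantile-regression trend, so a value of 1 means
#' "exactly at the median of peers at the same gestational age".
#'
#' @inheritParams fit_mom_model
#' @param model A `sh_mom_model` from [fit_mom_model()].
#' @return Object of the same shape as `x`, MoM-normalized.
#' @export
mom_normalize <- function(x, gestational_age, model) {
  stopifnot(inherits(model, "sh_mom_model"))
  is_feat <- inherits(x, "sh_features")
  m <- if (is_feat) feature_matrix(x) else as.matrix(x)
  if (any(gestational_age < model$ga_range[1] | gestational_age > model$ga_range[2], na.rm = TRUE)) {
    rlang::inform("MoM: gestational ages outside the fitted range; extrapolating the linear trend")
  }
  for (j in colnames(m)) {
    if (!j %in% names(model$intercept)) next
    pred <- exp(model$intercept[[j]] + model$slope[[j]] * gestational_age)
    if (any(!is.finite(pred) | pred <= 0)) stop("predicted median non-positive for column ", j, call. = FALSE)
    m[, j] <- m[, j] / pred
  }
  if (is_feat) {
    for (j in colnames(m)) x[[j]] <- unname(m[, j])
    attr(x, "mom") <- TRUE
    x
  } else {
    m
  }
}

#' Run the full metabolite-side preprocessing pipeline
#'
#' Fixed order: LOD imputation on the ng/mL matrix, conversion to umol/L,
#' specific-gravity correction, feature derivation (ratio features from the
#' pre-correction molar matrix), MoM gestational-age normalization of all
#' features, log2 transform.
#'
#' @param cohort A raw `sh_cohort` in ng/mL.
#' @param registry A `sh_registry`.
#' @param seed Integer seed controlling LOD imputation.
#' @param mom_derived Normalize derived ratio features by MoM as well as
#'   individual metabolites (default `TRUE`).
#' @return List with `features` (log2 MoM feature tibble), `features_mom`
#'   (pre-log2), `sg_model`, `mom_model`, and the molar matrices
#'   `conc_molar` (SG-corrected) and `conc_molar_raw`.
#' @export
preprocess_cohort <- function(cohort, registry, seed = 1L, mom_derived = TRUE) {
  stopifnot(inherits(registry, "sh_registry"))
  imp <- impute_cohort_lod(cohort, registry, seed = seed)
  molar_raw <- convert_cohort_to_molar(imp, registry)
  sg_model <- fit_sg_correction(molar_raw)
  molar_sg <- apply_sg_correction(molar_raw, sg_model)
  feats <- derive_features(molar_sg, registry, conc_raw = molar_raw)
  cls <- feature_classes(feats)
  mom_cols <- if (mom_derived) names(cls) else names(cls)[cls == "individual"]
  mom_model <- fit_mom_model(
    feature_matrix(feats)[, mom_cols, drop = FALSE],
    cohort$gestational_age_weeks
  )
  feats_mom <- mom_normalize(feats, cohort$gestational_age_weeks, mom_model)
  list(
    features = log2_features(feats_mom),
    features_mom = feats_mom,
    sg_model = sg_model,
    mom_model = mom_model,
    conc_molar = molar_sg,
    conc_molar_raw = molar_raw
  )
}
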