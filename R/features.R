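#' Derive the SH molecular feature matrix
#'
#' Expands a subjects x metabolites molar concentration matrix into the full
#' outcome feature set: one column per individual metabolite, plus one per
#' derived definition in the registry (sums, sulfate/glucuronide ratios,
#' enzyme product/precursor ratios). Sums are computed on the
#' dilution-corrected matrix; ratio features are computed on the raw
#' (uncorrected) molar concentrations, because a per-subject multiplicative
#' dilution factor cancels in a ratio and correcting first would only
#' propagate fitting noise. Pass the uncorrected matrix as `conc_raw`; with
#' `conc_raw = NULL` ratios are computed from `conc` itself.
#'
#' @param conc A `sh_cohort` in umol/L (individual metabolites and sums are
#'   read from here; typically SG-corrected).
#' @param registry A `sh_registry`.
#' @param conc_raw Optional `sh_cohort` in umol/L with uncorrected
#'   concentrations used for the ratio features.
#' @return A `sh_features` tibble: `subject_id` plus one numeric column per
#'   feature, with a named `feature_class` attribute
#'   (individual/sum/sg_ratio/enzyme_ratio). A zero denominator yields `NA`
#'   for that subject, never an infinity.
#' @export
derive_features <- function(conc, registry, conc_raw = NULL) {
  stopifnot(inherits(registry, "sh_registry"))
  if (cohort_unit(conc) != "umol_l") {
    stop("derive_features() needs molar concentrations (umol/L); got unit '",
      cohort_unit(conc), "'",
      call. = FALSE
    )
  }
  conc_raw <- conc_raw %||% conc
  if (cohort_unit(conc_raw) != "umol_l") {
    stop("conc_raw must be in umol/L", call. = FALSE)
  }
  ids <- registry$metabolites$id
  missing_ids <- setdiff(ids, names(conc))
  if (length(missing_ids)) {
    stop("cohort matrix lacks metabolite column(s): ", paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  m_corr <- conc_matrix(conc, ids)
  m_raw <- conc_matrix(conc_raw, ids)
  if (!identical(dim(m_corr), dim(m_raw))) stop("conc and conc_raw must cover the same subjects", call. = FALSE)

  der <- registry$derived
  out <- list()
  classes <- c(stats::setNames(rep("individual", length(ids)), ids))
  for (id in ids) out[[id]] <- unname(m_corr[, id])
  row_sum <- function(m, cols) {
    if (length(cols) == 1L) m[, cols] else rowSums(m[, cols, drop = FALSE])
  }
  for (i in seq_len(nrow(der))) {
    fid <- der$id[i]
    num <- der$numerator_ids[[i]]
    den <- der$denominator_ids[[i]]
    if (der$feature_class[i] == "sum") {
      v <- row_sum(m_corr, num)
    } else {
      nu <- row_sum(m_raw, num)
      de <- row_sum(m_raw, den)
      v <- ifelse(de > 0, nu / de, NA_real_)
    }
    out[[fid]] <- unname(v)
    classes[fid] <- der$feature_class[i]
  }
  res <- tibble::as_tibble(c(list(subject_id = conc$subject_id), out))
  attr(res, "feature_class") <- classes
  class(res) <- c("sh_features", class(res))
  res
}

feature_classes <- function(features) {
  cls <- attr(features, "feature_class")
  if (is.null(cls)) {
    cols <- setdiff(names(features), "subject_id")
    cls <- stats::setNames(rep("individual", length(cols)), cols)
  }
  cls
}

feature_matrix <- function(features) {
  cols <- setdiff(names(features), "subject_id")
  m <- as.matrix(as.data.frame(features)[, cols, drop = FALSE])
  rownames(m) <- features$subject_id
  storage.mode(m) <- "double"
  m
}

#' log2-transform a feature matrix
#'
#' Outcomes are log2-transformed before modelling to approximate normality.
#' All values must be strictly positive (guaranteed after LOD imputation).
#'
#' @param features A `sh_features` tibble.
#' @return The same tibble with every feature column log2-transformed and a
#'   `log2 = TRUE` attribute.
#' @export
log2_features <- function(features) {
  cols <- setdiff(names(features), "subject_id")
  for (j in cols) {
    v <- features[[j]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      stop(
        "non-positive value in feature '", j, "' (subject ",
        features$subject_id[bad[1]], "); log2 transform undefined",
        call. = FALSE
      )
    }
    features[[j]] <- log2(v)
  }
  attr(features, "log2") <- TRUE
  features
}
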