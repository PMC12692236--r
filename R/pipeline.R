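#' Run the full two-cohort determinant-mapping study
#'
#' End-to-end orchestration on a primary and (optionally) a replication
#' cohort: metabolite preprocessing, determinant preparation, exposome-wide
#' scan with ENT thresholds, bootstrap-stable elastic-net selection, LMG
#' variance decomposition, and replication of the primary pairs. All
#' randomness is keyed off `seed`; identical inputs and seed give
#' identical output.
#'
#' @param primary List with `cohort` (raw ng/mL `sh_cohort`) and
#'   `determinants` (`sh_determinants`), e.g. from [generate_cohort()].
#' @param replication Optional list of the same shape for the second
#'   cohort.
#' @param registry A `sh_registry`.
#' @param B Bootstrap replications for stability selection (default 100).
#' @param freq_threshold Stability threshold (default 0.8).
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param seed Master seed.
#' @return A `sh_study` list: `features`, `exposures`, `exwas`, `ent`,
#'   `associations`, `selection`, `variance` (decompositions + summary),
#'   `pairs`, and (with a replication cohort) `replication` +
#'   `replication_summary`.
#' @export
run_study <- function(primary, replication = NULL, registry = default_registry(),
                      B = 100, freq_threshold = 0.8, alpha = 0.5, seed = 1L) {
  prep <- preprocess_cohort(primary$cohort, registry, seed = seed)
  dprep <- prepare_determinants(primary$determinants, seed = seed + 1L)
  features <- align_subjects(prep$features, dprep$exposures)
  exposures <- align_subjects(dprep$exposures, features)

  scan <- fit_exwas(features, exposures)
  ent <- ent_thresholds(features, exposures)
  assoc <- classify_associations(scan, ent)

  selection <- select_all_features(features, exposures,
    B = B,
    freq_threshold = freq_threshold, alpha = alpha, seed = seed + 2L
  )
  decomps <- decompose_all_features(features, exposures, selection, seed = seed + 3L)
  variance <- summarize_variance(
    decomps,
    feature_class = feature_classes(features),
    family = determinant_families(exposures)
  )
  pairs <- primary_pairs(features, exposures, selection)

  out <- list(
    features = features, exposures = exposures,
    exwas = scan, ent = ent, associations = assoc,
    selection = selection, decompositions = decomps, variance = variance,
    pairs = pairs
  )
  if (!is.null(replication)) {
    prep2 <- preprocess_cohort(replication$cohort, registry, seed = seed + 10L)
    dprep2 <- prepare_determinants(replication$determinants, seed = seed + 11L)
    features2 <- align_subjects(prep2$features, dprep2$exposures)
    exposures2 <- align_subjects(dprep2$exposures, features2)
    repl <- replicate_pairs(pairs, features2, exposures2)
    out$replication <- repl
    out$replication_summary <- summarize_replication(repl)
  }
  class(out) <- "sh_study"
  out
}

# map determinant -> family from an exposure design
determinant_families <- function(exposures) {
  det <- attr(exposures, "determinant")
  fam <- attr(exposures, "family")
  stats::setNames(fam[!duplicated(det)], det[!duplicated(det)])
}

# restrict x to the subjects present in y (same order as x)
align_subjects <- function(x, y) {
  keep <- x$subject_id %in% y$subject_id
  out <- x[keep, , drop = FALSE]
  for (a in c("feature_class", "determinant", "family", "forced", "log2", "mom")) {
    if (!is.null(attr(x, a))) attr(out, a) <- attr(x, a)
  }
  class(out) <- class(x)
  out
}
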