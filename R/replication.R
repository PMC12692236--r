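# Second-cohort replication: determinant-feature pairs selected in the
# primary cohort are re-tested in the replication cohort with the same
# linear framework and cohort-specific covariates. Selection is never
# re-run here.

#' Build the primary determinant-feature pair table
#'
#' Collects, for every feature, the stable exposures from the primary
#' stability selection and their coefficients from the final linear model
#' (exposure + all other stable exposures + forced covariates).
#'
#' @param features Primary `sh_features` (log2 MoM).
#' @param exposures Primary `sh_exposures`.
#' @param selection A `sh_selection` from [select_all_features()].
#' @return Tibble `feature`, `feature_class`, `exposure`, `determinant`,
#'   `beta_primary`.
#' @export
primary_pairs <- function(features, exposures, selection) {
  fm <- feature_matrix(features)
  cls <- feature_classes(features)
  Xfree <- exposure_matrix(exposures, forced = FALSE)
  Xforced <- exposure_matrix(exposures, forced = TRUE)
  det_map <- attr(exposures, "determinant")
  sel <- selection$selection
  rows <- list()
  for (fname in unique(sel$feature[sel$stable])) {
    cols <- sel$exposure[sel$feature == fname & sel$stable]
    fit <- fit_final_model(fm[, fname], Xfree[, cols, drop = FALSE], Xforced)
    rows[[fname]] <- tibble::tibble(
      feature = fname, feature_class = unname(cls[fname]),
      exposure = cols, determinant = unname(det_map[cols]),
      beta_primary = unname(fit$coefficients[cols])
    )
  }
  dplyr::bind_rows(rows)
}

#' Re-test primary pairs in a replication cohort
#'
#' For each (exposure, feature) pair, fits OLS of the replication-cohort
#' feature on that exposure plus the replication cohort's own forced
#' covariates. Pairs whose exposure column is absent from the replication
#' design are reported as not testable, never dropped silently.
#' Replication uses raw p < 0.05 with a direction-consistency flag (a zero
#' replication beta counts as inconsistent); no further multiplicity
#' correction is applied at this stage.
#'
#' @param pairs Pair table from [primary_pairs()] (columns `feature`,
#'   `exposure`, `determinant`, `beta_primary`).
#' @param features2 Replication `sh_features` (log2 MoM).
#' @param exposures2 Replication `sh_exposures`.
#' @param alpha Replication significance level (default 0.05).
#' @return A `sh_replication` tibble: per pair `beta_replication`,
#'   `p_replication`, `testable`, `direction_consistent`, `replicated`.
#' @export
replicate_pairs <- function(pairs, features2, exposures2, alpha = 0.05) {
  fm <- feature_matrix(features2)
  Xfree <- exposure_matrix(exposures2, forced = FALSE)
  Xforced <- exposure_matrix(exposures2, forced = TRUE)
  out <- pairs
  out$beta_replication <- NA_real_
  out$p_replication <- NA_real_
  out$testable <- pairs$exposure %in% colnames(Xfree) & pairs$feature %in% colnames(fm)
  for (i in seq_len(nrow(out))) {
    if (!out$testable[i]) next
    y <- fm[, out$feature[i]]
    X <- cbind(`(Intercept)` = 1, exposure = Xfree[, out$exposure[i]], Xforced)
    ok <- is.finite(y) & stats::complete.cases(X)
    qr_x <- qr(X[ok, , drop = FALSE])
    if (qr_x$rank < ncol(X)) next
    coefs <- qr.coef(qr_x, y[ok])
    res <- y[ok] - X[ok, , drop = FALSE] %*% coefs
    df <- sum(ok) - ncol(X)
    se <- sqrt(sum(res^2) / df * chol2inv(qr.R(qr_x))[2, 2])
    tval <- coefs[2] / se
    out$beta_replication[i] <- unname(coefs[2])
    out$p_replication[i] <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  }
  out$direction_consistent <- out$testable &
    !is.na(out$beta_replication) &
    sign(out$beta_primary) == sign(out$beta_replication) &
    out$beta_replication != 0
  out$replicated <- out$direction_consistent & !is.na(out$p_replication) & out$p_replication < alpha
  class(out) <- c("sh_replication", class(out))
  out
}

#' Summarize a replication analysis
#'
#' @param result A `sh_replication` tibble.
#' @return List of counts: pairs tested/testable/replicated, determinants
#'   testable and with at least one replicated pair, direction-consistency
#'   fraction among testable pairs, and a per-determinant table.
#' @export
summarize_replication <- function(result) {
  testable <- result[result$testable, , drop = FALSE]
  repl <- result[result$replicated, , drop = FALSE]
  per_det <- NULL
  if (nrow(testable)) {
    per_det <- dplyr::summarise(
      dplyr::group_by(testable, .data$determinant),
      n_pairs = dplyr::n(),
      n_replicated = sum(.data$replicated),
      n_consistent = sum(.data$direction_consistent),
      .groups = "drop"
    )
  }
  list(
    n_pairs = nrow(result),
    n_testable = nrow(testable),
    n_replicated = nrow(repl),
    n_determinants_testable = length(unique(testable$determinant)),
    n_determinants_replicated = length(unique(repl$determinant)),
    consistency_fraction = if (nrow(testable)) mean(testable$direction_consistent) else NA_real_,
    per_determinant = per_det
  )
}
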