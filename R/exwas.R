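# Exposome-wide association scan: one adjusted OLS fit per
# (exposure, feature) pair, then effective-number-of-tests (ENT)
# multiple-testing thresholds per outcome group.

#' Fit the exposome-wide association scan
#'
#' Fits one ordinary least-squares model per (exposure, feature) pair:
#' `feature ~ exposure + forced covariates`. Features are expected on the
#' log2 MoM scale and exposures IQR-scaled/dummy-coded, so a beta is the
#' log2 feature change per IQR of a continuous exposure or per indicator
#' level. Forced covariates are adjusted for but never tested.
#'
#' @param features A `sh_features` tibble (log2 MoM).
#' @param exposures A `sh_exposures` design from [dummy_code()]; its forced
#'   columns are used as covariates.
#' @return A `sh_exwas` tibble with one row per pair: `exposure`,
#'   `determinant`, `family`, `feature`, `feature_class`, `beta`, `se`,
#'   `t`, `p`, `n`. Rank-deficient pairs are flagged with `NA` statistics
#'   rather than failing the scan.
#' @export
fit_exwas <- function(features, exposures) {
  fm <- feature_matrix(features)
  cls <- feature_classes(features)
  xm <- exposure_matrix(exposures, forced = FALSE)
  cm <- exposure_matrix(exposures, forced = TRUE)
  if (nrow(fm) != nrow(xm)) stop("features and exposures cover different subjects", call. = FALSE)
  det_map <- attr(exposures, "determinant")
  fam_map <- attr(exposures, "family")

  rows <- vector("list", ncol(xm) * ncol(fm))
  k <- 0L
  for (j in seq_len(ncol(fm))) {
    y_all <- fm[, j]
    for (e in seq_len(ncol(xm))) {
      k <- k + 1L
      x <- xm[, e]
      design <- cbind(`(Intercept)` = 1, exposure = x, cm)
      ok <- is.finite(y_all) & stats::complete.cases(design)
      y <- y_all[ok]
      X <- design[ok, , drop = FALSE]
      n <- length(y)
      est <- c(beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_)
      if (n > ncol(X)) {
        qr_x <- qr(X)
        if (qr_x$rank == ncol(X)) {
          coefs <- qr.coef(qr_x, y)
          res <- y - X %*% coefs
          df <- n - ncol(X)
          sigma2 <- sum(res^2) / df
          xtxi <- chol2inv(qr.R(qr_x))
          se <- sqrt(sigma2 * xtxi[2, 2])
          tval <- unname(coefs[2]) / se
          est <- c(
            beta = unname(coefs[2]), se = se, t = tval,
            p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
          )
        }
      }
      rows[[k]] <- tibble::tibble(
        exposure = colnames(xm)[e],
        determinant = unname(det_map[colnames(xm)[e]]),
        family = unname(fam_map[colnames(xm)[e]]),
        feature = colnames(fm)[j],
        feature_class = unname(cls[colnames(fm)[j]]),
        beta = est[["beta"]], se = est[["se"]], t = est[["t"]], p = est[["p"]],
        n = n
      )
    }
  }
  res <- dplyr::bind_rows(rows)
  class(res) <- c("sh_exwas", class(res))
  res
}

#' Effective number of tests (Li & Ji eigenvalue estimator)
#'
#' Estimates the number of independent tests in a correlated block from
#' the eigenvalues of its correlation matrix:
#' `ENT = sum_i [ I(|l_i| >= 1) + (|l_i| - floor(|l_i|)) ]`.
#' An identity matrix gives `m`; a perfectly correlated block gives 1.
#'
#' @param correlation_matrix Square symmetric correlation matrix with unit
#'   diagonal.
#' @return ENT estimate, in `[1, m]`.
#' @export
effective_number_of_tests <- function(correlation_matrix) {
  m <- as.matrix(correlation_matrix)
  if (nrow(m) != ncol(m)) stop("correlation matrix must be square", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) stop("correlation matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(m) - 1)) > 1e-8) stop("correlation matrix must have unit diagonal", call. = FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * nrow(m)) {
    stop("correlation matrix is not positive semi-definite (min eigenvalue ", signif(min(ev), 3), ")", call. = FALSE)
  }
  a <- abs(ev)
  # guard the floor against eigenvalues at integers up to rounding error
  eps <- 1e-8
  ent <- sum((a >= 1 - eps) + (a - floor(a + eps)))
  min(max(ent, 1), nrow(m))
}

#' ENT-corrected significance thresholds per outcome group
#'
#' A separate ENT is computed for each feature class (individual
#' metabolites, sums, S/G ratios, enzyme ratios) from the correlation
#' matrix of its log2 features, and one ENT for the dummy-coded exposure
#' block; the group threshold is
#' `p_ent = alpha / (ENT_features_group * ENT_determinants)`.
#'
#' @param features A `sh_features` tibble (log2 MoM).
#' @param exposures A `sh_exposures` design.
#' @param alpha Family-wise level (default 0.05).
#' @return A `sh_ent` list: `groups` tibble (`feature_class`, `m`, `ent`,
#'   `p_ent`), `ent_determinants`, `alpha`.
#' @export
ent_thresholds <- function(features, exposures, alpha = 0.05) {
  fm <- feature_matrix(features)
  cls <- feature_classes(features)
  xm <- exposure_matrix(exposures, forced = FALSE)
  ent_x <- effective_number_of_tests(safe_cor(xm))
  groups <- lapply(unique(cls), function(g) {
    cols <- names(cls)[cls == g]
    ent_g <- if (length(cols) == 1L) 1 else effective_number_of_tests(safe_cor(fm[, cols, drop = FALSE]))
    tibble::tibble(
      feature_class = g, m = length(cols), ent = ent_g,
      p_ent = alpha / (ent_g * ent_x)
    )
  })
  res <- list(groups = dplyr::bind_rows(groups), ent_determinants = ent_x, alpha = alpha)
  class(res) <- "sh_ent"
  res
}

# pairwise-complete correlation, symmetrized, zero-variance-safe
safe_cor <- function(m) {
  cm <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  (cm + t(cm)) / 2
}

#' Classify scan results against ENT thresholds
#'
#' Flags each association as significant within its outcome group, adds a
#' signed `-log10(p)` column (Miami-plot-ready), and tallies significant,
#' positive and negative associations overall and per determinant.
#'
#' @param result A `sh_exwas` tibble.
#' @param thresholds A `sh_ent` from [ent_thresholds()], or a single
#'   numeric p threshold applied to all groups.
#' @return List with the annotated `table` and a `summary` list
#'   (`n_significant`, `n_positive`, `n_negative`, `per_determinant`).
#' @export
classify_associations <- function(result, thresholds) {
  tab <- tibble::as_tibble(result)
  if (inherits(thresholds, "sh_ent")) {
    tab <- dplyr::left_join(
      tab, thresholds$groups[, c("feature_class", "p_ent")],
      by = "feature_class"
    )
  } else {
    tab$p_ent <- as.numeric(thresholds)
  }
  tab$significant <- !is.na(tab$p) & tab$p < tab$p_ent
  tab$signed_log10_p <- sign(tab$beta) * -log10(pmax(tab$p, .Machine$double.xmin))
  sig <- tab[tab$significant, , drop = FALSE]
  per_det <- sort(table(sig$determinant), decreasing = TRUE)
  list(
    table = tab,
    summary = list(
      n_significant = nrow(sig),
      n_positive = sum(sig$beta > 0, na.rm = TRUE),
      n_negative = sum(sig$beta < 0, na.rm = TRUE),
      per_determinant = per_det
    )
  )
}
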