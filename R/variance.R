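# Final per-feature linear models on the stable determinants, and LMG
# (Shapley) decomposition of the model R2 into per-determinant shares:
# sequential R2 increments averaged over all orderings of the predictor
# groups. The dummy indicators of one categorical determinant form a
# single group and enter/leave together. Forced covariates sit in every
# model but are partialled into the baseline, so shares sum to
# R2(full) - R2(covariates-only).

#' Fit the final linear model for one feature
#'
#' Ordinary least squares of one log2 feature on its stable exposure
#' columns plus the forced covariates. With an empty stable set this is
#' the covariates-only model.
#'
#' @param y Numeric outcome.
#' @param stable_X Matrix of stable exposure columns (may have 0 columns).
#' @param forced_X Matrix of forced covariate columns (may be `NULL`).
#' @return List with `coefficients`, `r2`, `residuals`, `fitted`, `n`.
#'   A collinear design is an error naming the aliased columns.
#' @export
fit_final_model <- function(y, stable_X, forced_X = NULL) {
  stable_X <- as.matrix(stable_X)
  X <- cbind(`(Intercept)` = 1, stable_X, forced_X)
  ok <- is.finite(y) & stats::complete.cases(X)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[-qr_x$pivot[seq_len(qr_x$rank)]]
    stop("final design is collinear; aliased column(s): ", paste(aliased, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qr_x, y)
  fitted <- as.numeric(X %*% coefs)
  res <- y - fitted
  tss <- sum((y - mean(y))^2)
  list(
    coefficients = coefs,
    r2 = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
    residuals = res, fitted = fitted, n = length(y)
  )
}

rsq <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    return(NA_real_)
  }
  1 - sum(fit$residuals^2) / tss
}

#' LMG decomposition of explained variance
#'
#' Attributes shares of the model R2 to predictor groups by averaging each
#' group's sequential R2 increment over orderings of the groups (the
#' Shapley value of the R2 game). With at most `exact_max_groups` groups
#' every ordering is enumerated exactly (via subset R2 caching); above
#' that, orderings are sampled uniformly at random.
#'
#' @param y Numeric outcome.
#' @param X Numeric design matrix holding all grouped predictor columns.
#' @param groups Named list mapping each group (a determinant) to its
#'   column names in `X`; dummies of one categorical form one group.
#' @param covariates Optional matrix of forced covariates included in
#'   every submodel but carrying no share.
#' @param exact_max_groups Exact-enumeration limit (default 10).
#' @param n_perm Sampled orderings above the limit (default 5000).
#' @param seed Seed for the sampled mode.
#' @return A `sh_lmg` list: `shares` tibble (`group`, `share`),
#'   `total_r2` (full model), `baseline_r2` (covariates-only),
#'   `exact` flag.
#' @export
lmg_decomposition <- function(y, X, groups, covariates = NULL,
                              exact_max_groups = 10, n_perm = 5000, seed = 1L) {
  X <- as.matrix(X)
  base_X <- cbind(rep(1, nrow(X)), covariates)
  ok <- is.finite(y) & stats::complete.cases(X) & stats::complete.cases(base_X)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  base_X <- base_X[ok, , drop = FALSE]
  g <- length(groups)
  baseline_r2 <- rsq(y, base_X)
  if (g == 0) {
    res <- list(
      shares = tibble::tibble(group = character(0), share = numeric(0)),
      total_r2 = baseline_r2, baseline_r2 = baseline_r2, exact = TRUE
    )
    class(res) <- "sh_lmg"
    return(res)
  }
  missing_cols <- setdiff(unlist(groups), colnames(X))
  if (length(missing_cols)) stop("group columns absent from X: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  gnames <- names(groups)

  subset_r2 <- function(mask) {
    cols <- unlist(groups[mask], use.names = FALSE)
    rsq(y, cbind(base_X, X[, cols, drop = FALSE]))
  }
  shares <- stats::setNames(numeric(g), gnames)
  exact <- g <= exact_max_groups
  if (exact) {
    r2_cache <- numeric(2^g)
    for (s in 0:(2^g - 1)) {
      mask <- as.logical(bitwAnd(s, 2^(0:(g - 1))))
      r2_cache[s + 1] <- subset_r2(mask)
    }
    fact <- factorial(0:g)
    for (j in seq_len(g)) {
      bit <- 2^(j - 1)
      for (s in 0:(2^g - 1)) {
        if (bitwAnd(s, bit) != 0) next
        size <- sum(as.logical(bitwAnd(s, 2^(0:(g - 1)))))
        w <- fact[size + 1] * fact[g - size] / fact[g + 1]
        shares[j] <- shares[j] + w * (r2_cache[s + bit + 1] - r2_cache[s + 1])
      }
    }
    total_r2 <- r2_cache[2^g]
  } else {
    withr::with_seed(seed, {
      for (p in seq_len(n_perm)) {
        ord <- sample.int(g)
        mask <- rep(FALSE, g)
        prev <- baseline_r2
        for (j in ord) {
          mask[j] <- TRUE
          cur <- subset_r2(mask)
          shares[j] <- shares[j] + (cur - prev)
          prev <- cur
        }
      }
    })
    shares <- shares / n_perm
    total_r2 <- subset_r2(rep(TRUE, g))
  }
  res <- list(
    shares = tibble::tibble(group = gnames, share = unname(shares)),
    total_r2 = total_r2, baseline_r2 = baseline_r2, exact = exact
  )
  class(res) <- "sh_lmg"
  res
}

#' Variance decomposition for every feature with a stable set
#'
#' For each feature, fits the final model on its stable determinants (all
#' dummy columns of a selected categorical enter as one group) plus forced
#' covariates, and decomposes the explained variance by LMG.
#'
#' @param features A `sh_features` tibble (log2 MoM).
#' @param exposures A `sh_exposures` design.
#' @param selection A `sh_selection` from [select_all_features()].
#' @param seed Seed (sampled LMG mode).
#' @return Named list of `sh_lmg` objects, one per feature.
#' @export
decompose_all_features <- function(features, exposures, selection, seed = 1L) {
  fm <- feature_matrix(features)
  Xfree <- exposure_matrix(exposures, forced = FALSE)
  Xforced <- exposure_matrix(exposures, forced = TRUE)
  det_map <- attr(exposures, "determinant")
  sel <- selection$selection
  out <- list()
  for (fname in colnames(fm)) {
    stable_dets <- unique(sel$determinant[sel$feature == fname & sel$stable])
    groups <- lapply(
      stats::setNames(stable_dets, stable_dets),
      function(d) names(det_map)[det_map == d & names(det_map) %in% colnames(Xfree)]
    )
    groups <- groups[lengths(groups) > 0]
    cols <- unlist(groups, use.names = FALSE)
    out[[fname]] <- lmg_decomposition(
      fm[, fname], Xfree[, cols, drop = FALSE], groups,
      covariates = Xforced, seed = seed
    )
  }
  out
}

#' Long-format summary of variance decompositions
#'
#' @param decompositions Named list of `sh_lmg` (per feature), e.g. from
#'   [decompose_all_features()].
#' @param feature_class Optional named vector feature -> class.
#' @param family Optional named vector determinant -> family.
#' @return List with `table` (feature, feature_class, group, family,
#'   share, total_r2) and `max_r2` across features.
#' @export
summarize_variance <- function(decompositions, feature_class = NULL, family = NULL) {
  rows <- purrr::imap(decompositions, function(d, fname) {
    if (!nrow(d$shares)) {
      return(NULL)
    }
    tibble::tibble(
      feature = fname,
      feature_class = if (!is.null(feature_class)) unname(feature_class[fname]) else NA_character_,
      group = d$shares$group,
      family = if (!is.null(family)) unname(family[d$shares$group]) else NA_character_,
      share = d$shares$share,
      total_r2 = d$total_r2,
      baseline_r2 = d$baseline_r2
    )
  })
  tab <- dplyr::bind_rows(rows)
  list(
    table = tab,
    max_r2 = if (length(decompositions)) {
      max(vapply(decompositions, function(d) d$total_r2 - d$baseline_r2, numeric(1)), na.rm = TRUE)
    } else {
      NA_real_
    }
  )
}
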