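# Per-feature multivariable selection: elastic net (alpha = 0.5) with
# forced (unpenalized) covariates, lambda chosen by 10-fold CV at minimum
# mean squared error, and 100-bootstrap stability filtering at an 80%
# selection-frequency threshold.

#' Fit an elastic net for one outcome feature
#'
#' Fits a mixed L1/L2 penalized regression of one log2 feature on the
#' exposure design. The penalty weight lambda is chosen by k-fold
#' cross-validation (minimum CV mean squared error by default; the
#' one-standard-error rule is available). Forced covariates receive a zero
#' penalty factor so they are always in the model. An 80/20 train-test
#' split is used: the model is fitted and cross-validated on the training
#' portion and the held-out mean squared error is reported as a
#' diagnostic.
#'
#' @param y Numeric outcome vector (one log2 feature).
#' @param X Numeric design matrix: exposures plus forced covariates.
#' @param forced Character vector of column names of `X` forced into the
#'   model (zero penalty).
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param folds CV folds (default 10).
#' @param seed Integer seed (fold assignment and split).
#' @param lambda_rule `"min"` (lambda at minimum CV-MSE) or `"1se"`.
#' @param lambda Optional fixed lambda; skips cross-validation.
#' @param train_fraction Fraction used for training (default 0.8; `1`
#'   disables the split).
#' @param ... Passed to [glmnet::glmnet()] (e.g. `standardize`,
#'   `intercept`, `thresh`).
#' @return A `sh_enet` list: `coefficients` (named, at the chosen lambda),
#'   `nonzero` (non-forced columns with nonzero coefficient), `lambda`,
#'   `alpha`, `test_mse`, `train_idx`, `cv` (the cv.glmnet object or
#'   `NULL`).
#' @export
fit_enet <- function(y, X, forced = character(0), alpha = 0.5, folds = 10, seed = 1L,
                     lambda_rule = c("min", "1se"), lambda = NULL,
                     train_fraction = 0.8, ...) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  ok <- is.finite(y) & stats::complete.cases(X)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  if (stats::sd(y) == 0) stop("constant outcome; elastic net undefined", call. = FALSE)
  bad <- setdiff(forced, colnames(X))
  if (length(bad)) stop("forced column(s) not in X: ", paste(bad, collapse = ", "), call. = FALSE)
  pf <- ifelse(colnames(X) %in% forced, 0, 1)

  withr::with_seed(seed, {
    n <- length(y)
    if (train_fraction < 1) {
      idx <- sample.int(n, size = max(floor(train_fraction * n), 2))
    } else {
      idx <- seq_len(n)
    }
    y_tr <- y[idx]
    X_tr <- X[idx, , drop = FALSE]
    if (is.null(lambda)) {
      if (length(y_tr) <= folds) stop("too few observations for ", folds, "-fold CV", call. = FALSE)
      foldid <- sample(rep(seq_len(folds), length.out = length(y_tr)))
      cv <- glmnet::cv.glmnet(X_tr, y_tr,
        alpha = alpha, penalty.factor = pf,
        foldid = foldid, type.measure = "mse", ...
      )
      lambda <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
    } else {
      cv <- NULL
    }
    fit <- glmnet::glmnet(X_tr, y_tr,
      alpha = alpha, penalty.factor = pf,
      lambda = lambda_path(lambda), ...
    )
    co <- stats::coef(fit, s = lambda)
    coefs <- stats::setNames(as.numeric(co), rownames(co))
    test_mse <- NA_real_
    if (train_fraction < 1 && length(idx) < n) {
      pred <- as.numeric(stats::predict(fit, X[-idx, , drop = FALSE], s = lambda))
      test_mse <- mean((y[-idx] - pred)^2)
    }
  })
  nz <- setdiff(names(coefs)[coefs != 0], c("(Intercept)", forced))
  res <- list(
    coefficients = coefs, nonzero = nz, lambda = lambda, alpha = alpha,
    forced = forced, test_mse = test_mse, train_idx = idx, cv = cv
  )
  class(res) <- "sh_enet"
  res
}

# short descending path ending at the target lambda: glmnet converges more
# reliably along a path than from a cold start at a single value
lambda_path <- function(lambda) {
  if (lambda <= 0) {
    return(lambda)
  }
  lambda * c(16, 8, 4, 2, 1)
}

#' Bootstrap stability of elastic-net selection
#'
#' Re-fits the elastic net on bootstrap resamples (subjects drawn with
#' replacement, original n, from the training portion) at the lambda
#' chosen once by cross-validation, and records for each non-forced
#' exposure the fraction of resamples in which its coefficient is nonzero.
#' Exposures at or above the frequency threshold are flagged stable.
#'
#' @inheritParams fit_enet
#' @param B Number of bootstrap replications (default 100).
#' @param freq_threshold Stability threshold on the selection frequency
#'   (default 0.8).
#' @return A `sh_stability` list: tibble `selection` (`exposure`,
#'   `frequency`, `stable`, `coef_sign` from the full training fit),
#'   `fit` (the underlying `sh_enet`), `B`, `freq_threshold`.
#' @export
bootstrap_stability <- function(y, X, forced = character(0), B = 100, freq_threshold = 0.8,
                                seed = 1L, alpha = 0.5, folds = 10, ...) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  X <- as.matrix(X)
  base <- fit_enet(y, X, forced = forced, alpha = alpha, folds = folds, seed = seed, ...)
  ok <- is.finite(y) & stats::complete.cases(X)
  y_tr <- y[ok][base$train_idx]
  X_tr <- X[ok, , drop = FALSE][base$train_idx, , drop = FALSE]
  pf <- ifelse(colnames(X) %in% forced, 0, 1)
  free <- setdiff(colnames(X), forced)
  count <- stats::setNames(numeric(length(free)), free)
  withr::with_seed(seed + 1L, {
    n <- length(y_tr)
    for (b in seq_len(B)) {
      take <- sample.int(n, n, replace = TRUE)
      fit <- glmnet::glmnet(X_tr[take, , drop = FALSE], y_tr[take],
        alpha = alpha, penalty.factor = pf, lambda = lambda_path(base$lambda), ...
      )
      co <- stats::coef(fit, s = base$lambda)
      nz <- rownames(co)[as.numeric(co) != 0]
      hit <- intersect(nz, free)
      count[hit] <- count[hit] + 1
    }
  })
  freq <- count / B
  res <- list(
    selection = tibble::tibble(
      exposure = free,
      frequency = unname(freq),
      stable = unname(freq >= freq_threshold),
      coef_sign = sign(base$coefficients[free])
    ),
    fit = base, B = B, freq_threshold = freq_threshold
  )
  class(res) <- "sh_stability"
  res
}

#' Stability selection across all features
#'
#' Runs [bootstrap_stability()] for every feature column, with per-feature
#' seed offsets from one master seed so results are reproducible and
#' independent of execution order.
#'
#' @param features A `sh_features` tibble (log2 MoM).
#' @param exposures A `sh_exposures` design (forced columns are taken from
#'   its `forced` attribute).
#' @param B,freq_threshold,alpha,folds See [bootstrap_stability()].
#' @param seed Master seed.
#' @return A `sh_selection` list: `selection` long tibble (`feature`,
#'   `feature_class`, `exposure`, `determinant`, `frequency`, `stable`,
#'   `coef_sign`), and `summary` (features with at least one stable
#'   determinant, distinct stable determinants).
#' @export
select_all_features <- function(features, exposures, B = 100, freq_threshold = 0.8,
                                alpha = 0.5, folds = 10, seed = 1L) {
  fm <- feature_matrix(features)
  cls <- feature_classes(features)
  Xfree <- exposure_matrix(exposures, forced = FALSE)
  Xforced <- exposure_matrix(exposures, forced = TRUE)
  X <- cbind(Xfree, Xforced)
  det_map <- attr(exposures, "determinant")
  out <- vector("list", ncol(fm))
  for (j in seq_len(ncol(fm))) {
    fname <- colnames(fm)[j]
    st <- bootstrap_stability(fm[, j], X,
      forced = colnames(Xforced), B = B,
      freq_threshold = freq_threshold, alpha = alpha, folds = folds,
      seed = seed + 1000L * j
    )
    sel <- st$selection
    sel$feature <- fname
    sel$feature_class <- unname(cls[fname])
    sel$determinant <- unname(det_map[sel$exposure])
    out[[j]] <- sel
  }
  selection <- dplyr::bind_rows(out)
  stable <- selection[selection$stable, , drop = FALSE]
  res <- list(
    selection = selection,
    summary = list(
      n_features = ncol(fm),
      n_features_with_stable = length(unique(stable$feature)),
      n_features_without_stable = ncol(fm) - length(unique(stable$feature)),
      n_stable_determinants = length(unique(stable$determinant))
    )
  )
  class(res) <- "sh_selection"
  res
}
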