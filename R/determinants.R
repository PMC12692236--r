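# Determinant-side preparation, in the fixed order:
# missingness filter -> correlation pruning -> iterative RF imputation ->
# IQR scaling -> dummy coding.

#' Construct a determinant table
#'
#' @param data Tibble with `subject_id` and one column per determinant;
#'   categorical columns may be character or factor.
#' @param schema Tibble describing each column: `id`, `type` ("continuous"
#'   or "categorical"), `family` (sociodemographic/clinical/lifestyle/
#'   mental_health/genetic/fetal/technical), list-column `levels`
#'   (ordered level set, categorical only), `reference` (reference level,
#'   `NA` = most frequent), logical `forced` (technical covariates forced
#'   into every model).
#' @return A `sh_determinants` object (list with `data` and `schema`).
#' @export
sh_determinants <- function(data, schema) {
  data <- tibble::as_tibble(data)
  if (!"subject_id" %in% names(data)) stop("determinant table needs a subject_id column", call. = FALSE)
  schema <- tibble::as_tibble(schema)
  need <- c("id", "type", "family", "forced")
  miss <- setdiff(need, names(schema))
  if (length(miss)) stop("schema lacks field(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"levels" %in% names(schema)) schema$levels <- rep(list(NULL), nrow(schema))
  if (!"reference" %in% names(schema)) schema$reference <- NA_character_
  absent <- setdiff(schema$id, names(data))
  if (length(absent)) stop("schema columns absent from data: ", paste(absent, collapse = ", "), call. = FALSE)
  for (k in which(schema$type == "categorical")) {
    id <- schema$id[k]
    lev <- schema$levels[[k]] %||% sort(unique(stats::na.omit(as.character(data[[id]]))))
    schema$levels[[k]] <- lev
    vals <- as.character(data[[id]])
    bad <- setdiff(unique(stats::na.omit(vals)), lev)
    if (length(bad)) {
      stop("column '", id, "' has undeclared level(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    data[[id]] <- factor(vals, levels = lev)
  }
  out <- list(data = data, schema = schema)
  class(out) <- "sh_determinants"
  out
}

det_cols <- function(det) det$schema$id

#' Filter rows and columns by missingness
#'
#' Subjects with more than `row_max` missing determinant data are removed
#' first, then determinant columns with more than `col_max` missing data.
#'
#' @param det A `sh_determinants`.
#' @param row_max,col_max Maximum tolerated missing fraction (default 0.5).
#' @return List with the filtered `sh_determinants` and a `report` listing
#'   `rows_removed` (subject ids) and `cols_removed`.
#' @export
filter_missingness <- function(det, row_max = 0.5, col_max = 0.5) {
  stopifnot(row_max > 0, row_max <= 1, col_max > 0, col_max <= 1)
  d <- det$data
  cols <- det_cols(det)
  miss <- is.na(as.data.frame(d[, cols]))
  row_frac <- rowMeans(miss)
  drop_rows <- which(row_frac > row_max)
  rows_removed <- d$subject_id[drop_rows]
  if (length(drop_rows)) {
    d <- d[-drop_rows, , drop = FALSE]
    miss <- miss[-drop_rows, , drop = FALSE]
  }
  if (!nrow(d)) stop("all subjects removed by the missingness filter", call. = FALSE)
  col_frac <- colMeans(miss)
  cols_removed <- cols[col_frac > col_max]
  if (length(cols_removed)) {
    d <- d[, setdiff(names(d), cols_removed), drop = FALSE]
  }
  schema <- det$schema[!det$schema$id %in% cols_removed, , drop = FALSE]
  out <- list(data = d, schema = schema)
  class(out) <- "sh_determinants"
  list(
    determinants = out,
    report = list(rows_removed = rows_removed, cols_removed = cols_removed)
  )
}

#' Prune highly correlated continuous determinants
#'
#' Pairs of continuous columns with `|r| > r_max` are resolved greedily in
#' descending `|r|`: the member with the higher mean absolute correlation
#' to all other continuous columns is dropped (ties broken by column
#' order). Categorical columns are never pruned.
#'
#' @param det A `sh_determinants`.
#' @param r_max Correlation threshold (default 0.9).
#' @return List with the pruned `sh_determinants` and a `report` of dropped
#'   columns with the offending correlation.
#' @export
prune_correlated <- function(det, r_max = 0.9) {
  cont <- det$schema$id[det$schema$type == "continuous" & !det$schema$forced]
  dropped <- character(0)
  detail <- list()
  if (length(cont) >= 2) {
    x <- as.data.frame(det$data[, cont])
    cm <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
    cm[is.na(cm)] <- 0
    keep <- cont
    repeat {
      sub <- abs(cm[keep, keep, drop = FALSE])
      diag(sub) <- 0
      if (!length(sub) || max(sub) <= r_max) break
      idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      a <- keep[idx[1]]
      b <- keep[idx[2]]
      mean_r <- function(v) mean(abs(cm[v, setdiff(keep, v)]))
      drop <- if (mean_r(a) > mean_r(b)) {
        a
      } else if (mean_r(b) > mean_r(a)) {
        b
      } else {
        keep[max(match(c(a, b), cont))] # tie: later column order
      }
      detail[[drop]] <- max(sub)
      dropped <- c(dropped, drop)
      keep <- setdiff(keep, drop)
    }
  }
  out <- list(
    data = det$data[, setdiff(names(det$data), dropped), drop = FALSE],
    schema = det$schema[!det$schema$id %in% dropped, , drop = FALSE]
  )
  class(out) <- "sh_determinants"
  list(determinants = out, report = list(cols_removed = dropped, max_r = detail))
}

mode_level <- function(f) names(sort(table(f), decreasing = TRUE))[1]

#' Iterative random-forest imputation of mixed-type determinants
#'
#' missForest-style chained imputation: missing cells are initialized with
#' the column median (continuous) or mode (categorical), then each column
#' with missing values is re-imputed in turn by a random forest trained on
#' the currently completed other columns (regression trees for continuous,
#' classification for categorical). Iteration stops when the change
#' criterion (normalized squared change for continuous plus category
#' mismatch proportion for categorical) first increases, or after
#' `max_iter` sweeps; the result from the last improving sweep is kept.
#' Observed cells are never altered.
#'
#' @param det A `sh_determinants` (post filtering/pruning).
#' @param seed Integer seed; the result is deterministic given it.
#' @param max_iter Maximum sweeps (default 10).
#' @param ntree Trees per forest (default 50).
#' @return A completed `sh_determinants`.
#' @export
impute_iterative <- function(det, seed = 1L, max_iter = 10L, ntree = 50L) {
  d <- det$data
  cols <- det_cols(det)
  n_miss <- vapply(cols, function(j) sum(is.na(d[[j]])), integer(1))
  all_missing <- cols[n_miss == nrow(d)]
  if (length(all_missing)) {
    stop("column(s) entirely missing (filter first): ", paste(all_missing, collapse = ", "), call. = FALSE)
  }
  targets <- cols[n_miss > 0]
  if (!length(targets)) {
    return(det)
  }
  targets <- targets[order(n_miss[targets])]
  obs_mask <- lapply(stats::setNames(targets, targets), function(j) !is.na(d[[j]]))
  cur <- d
  # initialization: median / mode
  for (j in cols) {
    if (!any(is.na(cur[[j]]))) next
    if (is.factor(cur[[j]])) {
      cur[[j]][is.na(cur[[j]])] <- mode_level(cur[[j]])
    } else {
      cur[[j]][is.na(cur[[j]])] <- stats::median(cur[[j]], na.rm = TRUE)
    }
  }
  best <- cur
  prev_crit <- Inf
  withr::with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      new <- cur
      for (j in targets) {
        ok <- obs_mask[[j]]
        x <- as.data.frame(new[, setdiff(cols, j)])
        names(x) <- make.names(names(x)) # RF formula-safe names
        y_obs <- d[[j]][ok]
        if (is.factor(y_obs)) y_obs <- droplevels(y_obs)
        if (is.factor(y_obs) && nlevels(y_obs) < 2) {
          new[[j]][!ok] <- levels(y_obs)[1]
        } else if (!is.factor(y_obs) && stats::sd(as.numeric(y_obs)) == 0) {
          new[[j]][!ok] <- y_obs[1]
        } else {
          rf <- suppressWarnings(
            randomForest::randomForest(x = x[ok, , drop = FALSE], y = y_obs, ntree = ntree)
          )
          pred <- stats::predict(rf, x[!ok, , drop = FALSE])
          new[[j]][!ok] <- if (is.factor(y_obs)) as.character(pred) else pred
        }
      }
      num <- 0
      den <- 0
      mis <- 0
      n_cat <- 0
      for (j in targets) {
        if (is.factor(new[[j]])) {
          mis <- mis + sum(new[[j]] != cur[[j]])
          n_cat <- n_cat + sum(!obs_mask[[j]])
        } else {
          num <- num + sum((as.numeric(new[[j]]) - as.numeric(cur[[j]]))^2)
          den <- den + sum(as.numeric(new[[j]])^2)
        }
      }
      crit <- (if (den > 0) num / den else 0) + (if (n_cat > 0) mis / n_cat else 0)
      if (crit >= prev_crit) break
      prev_crit <- crit
      best <- new
      cur <- new
    }
  })
  out <- list(data = best, schema = det$schema)
  class(out) <- "sh_determinants"
  out
}

#' IQR-scale a continuous column
#'
#' Centers at the median and scales by the interquartile range, so the
#' scaled column has median 0 and IQR 1. Robust standardization mitigates
#' the influence of outliers.
#'
#' @param x Numeric vector.
#' @param name Column name used in error messages.
#' @return Scaled numeric vector.
#' @export
iqr_scale <- function(x, name = deparse(substitute(x))) {
  iqr <- stats::IQR(x, na.rm = TRUE)
  if (!is.finite(iqr) || iqr == 0) stop("IQR is zero for column '", name, "'; cannot scale", call. = FALSE)
  (x - stats::median(x, na.rm = TRUE)) / iqr
}

#' Dummy-code determinants into an exposure design
#'
#' Continuous columns are IQR-scaled and passed through; a k-level
#' categorical becomes k-1 indicator columns named `var_level` for each
#' non-reference level. Forced technical covariates are dummy-coded the
#' same way but flagged so downstream models adjust for them without
#' testing or penalizing them.
#'
#' @param det A completed `sh_determinants` (no missing values).
#' @param scale_continuous IQR-scale continuous columns (default `TRUE`).
#' @return A `sh_exposures` tibble (`subject_id` + design columns) with
#'   attributes `determinant` (column -> source determinant), `family`,
#'   and `forced` (logical per column).
#' @export
dummy_code <- function(det, scale_continuous = TRUE) {
  d <- det$data
  out <- list(subject_id = d$subject_id)
  det_map <- character(0)
  fam_map <- character(0)
  forced <- logical(0)
  for (k in seq_len(nrow(det$schema))) {
    id <- det$schema$id[k]
    if (any(is.na(d[[id]]))) stop("column '", id, "' still has missing values; impute first", call. = FALSE)
    if (det$schema$type[k] == "continuous") {
      v <- as.numeric(d[[id]])
      if (scale_continuous && !det$schema$forced[k]) v <- iqr_scale(v, name = id)
      out[[id]] <- v
      det_map[id] <- id
      fam_map[id] <- det$schema$family[k]
      forced[id] <- det$schema$forced[k]
    } else {
      lev <- det$schema$levels[[k]]
      ref <- det$schema$reference[k]
      if (is.na(ref)) ref <- mode_level(d[[id]])
      if (!ref %in% lev) stop("reference level '", ref, "' not a level of '", id, "'", call. = FALSE)
      for (l in setdiff(lev, ref)) {
        cn <- paste(id, l, sep = "_")
        out[[cn]] <- as.numeric(d[[id]] == l)
        det_map[cn] <- id
        fam_map[cn] <- det$schema$family[k]
        forced[cn] <- det$schema$forced[k]
      }
    }
  }
  res <- tibble::as_tibble(out)
  attr(res, "determinant") <- det_map
  attr(res, "family") <- fam_map
  attr(res, "forced") <- forced
  class(res) <- c("sh_exposures", class(res))
  res
}

exposure_matrix <- function(exposures, forced = FALSE) {
  f <- attr(exposures, "forced")
  cols <- names(f)[f == forced]
  m <- as.matrix(as.data.frame(exposures)[, cols, drop = FALSE])
  rownames(m) <- exposures$subject_id
  m
}

#' Run the full determinant preparation chain
#'
#' Missingness filter, correlation pruning, iterative RF imputation and
#' dummy coding, in that fixed order.
#'
#' @param det A `sh_determinants`.
#' @param seed Integer seed (imputation).
#' @param row_max,col_max,r_max Filtering/pruning thresholds.
#' @return List with `exposures` (a `sh_exposures`), the completed
#'   `determinants`, and a preparation `report`.
#' @export
prepare_determinants <- function(det, seed = 1L, row_max = 0.5, col_max = 0.5, r_max = 0.9) {
  f <- filter_missingness(det, row_max = row_max, col_max = col_max)
  p <- prune_correlated(f$determinants, r_max = r_max)
  imp <- impute_iterative(p$determinants, seed = seed)
  exposures <- dummy_code(imp)
  list(
    exposures = exposures,
    determinants = imp,
    report = list(missingness = f$report, correlation = p$report)
  )
}
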