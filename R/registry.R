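#' The built-in steroid panel registry
#'
#' Returns the default panel registry: 50 conjugated urinary SH metabolites
#' covering the androgen, estrogen, progestogen and corticosteroid branches
#' of steroidogenesis, plus the definitions of 39 derived molecular features
#' (13 family/hormone-group sums, 9 sulfate/glucuronide ratios, 17
#' product/precursor enzyme-activity indices), for 89 outcome features in
#' total. All annotations (molar masses, LODs, derived-feature compositions)
#' are registry data and can be overridden by loading a custom registry with
#' [load_registry()].
#'
#' @return A `sh_registry` object: a list with tibbles `metabolites` and
#'   `derived`, and a `version` string.
#' @export
#' @examples
#' reg <- default_registry()
#' feature_counts(reg)
default_registry <- function() {
  panel <- sh_panel_table()
  metabolites <- tibble::tibble(
    id = panel$id,
    full_name = panel$full_name,
    hormone_group = panel$hormone_group,
    family = unname(sh_family_map[panel$hormone_group]),
    conjugation = conjugation_from_id(panel$id),
    molar_mass = panel$molar_mass,
    # default LODs: ~15% of the calibration median mass concentration,
    # clipped to the panel's working 1-200 ng/mL range
    lod = pmin(pmax(round(0.15 * panel$median_bisc * panel$molar_mass, 1), 1), 200)
  )
  reg <- list(
    metabolites = metabolites,
    derived = sh_derived_table(metabolites),
    version = "builtin-1.0"
  )
  class(reg) <- "sh_registry"
  validate_registry(reg)
  reg
}

#' Load a panel registry from a JSON file
#'
#' The file must contain a `metabolites` array (fields `id`, `full_name`,
#' `hormone_group`, `family`, `conjugation`, `molar_mass`, `lod`) and a
#' `derived` array (fields `id`, `feature_class`, `label`, `numerator_ids`,
#' `denominator_ids`). With `path = NULL` the built-in registry is returned.
#'
#' @param path Path to a registry JSON file, or `NULL` for the default.
#' @return A validated `sh_registry`.
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    return(default_registry())
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!all(c("metabolites", "derived") %in% names(raw))) {
    stop("registry file must contain 'metabolites' and 'derived' entries", call. = FALSE)
  }
  met <- tibble::as_tibble(raw$metabolites)
  der <- tibble::as_tibble(raw$derived)
  if (nrow(der)) {
    wrap <- function(x) if (is.list(x)) purrr::map(x, as.character) else as.list(as.character(x))
    der$numerator_ids <- wrap(der$numerator_ids)
    der$denominator_ids <- if ("denominator_ids" %in% names(der)) {
      purrr::map(wrap(der$denominator_ids), function(v) v[!is.na(v) & nzchar(v)])
    } else {
      rep(list(character(0)), nrow(der))
    }
  }
  reg <- list(
    metabolites = met, derived = der,
    version = if (!is.null(raw$version)) as.character(raw$version) else "custom"
  )
  class(reg) <- "sh_registry"
  validate_registry(reg)
  reg
}

#' Write a registry to JSON
#'
#' @param registry A `sh_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "sh_registry"))
  jsonlite::write_json(
    list(
      metabolites = registry$metabolites,
      derived = registry$derived,
      version = registry$version
    ),
    path,
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

validate_registry <- function(reg) {
  met <- reg$metabolites
  need <- c("id", "hormone_group", "family", "conjugation", "molar_mass", "lod")
  missing_fields <- setdiff(need, names(met))
  if (length(missing_fields)) {
    stop("registry metabolites lack fields: ", paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  dup <- met$id[duplicated(met$id)]
  if (length(dup)) stop("duplicate metabolite ids: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(met$molar_mass <= 0)) stop("molar_mass must be > 0", call. = FALSE)
  if (any(met$lod < 0)) stop("lod must be >= 0", call. = FALSE)
  implied <- conjugation_from_id(met$id)
  bad <- met$id[!is.na(implied) & implied != met$conjugation]
  if (length(bad)) {
    stop("conjugation inconsistent with id suffix for: ", paste(bad, collapse = ", "), call. = FALSE)
  }

  der <- reg$derived
  if (nrow(der)) {
    ddup <- der$id[duplicated(der$id)]
    if (length(ddup)) stop("duplicate derived feature ids: ", paste(unique(ddup), collapse = ", "), call. = FALSE)
    clash <- intersect(der$id, met$id)
    if (length(clash)) stop("derived ids collide with metabolite ids: ", paste(clash, collapse = ", "), call. = FALSE)
    ok_class <- der$feature_class %in% c("sum", "sg_ratio", "enzyme_ratio")
    if (!all(ok_class)) stop("unknown feature_class: ", paste(unique(der$feature_class[!ok_class]), collapse = ", "), call. = FALSE)
    for (i in seq_len(nrow(der))) {
      num <- der$numerator_ids[[i]]
      den <- der$denominator_ids[[i]]
      unknown <- setdiff(c(num, den), met$id)
      if (length(unknown)) {
        stop("derived feature '", der$id[i], "' references unknown metabolite id(s): ",
          paste(unknown, collapse = ", "),
          call. = FALSE
        )
      }
      if (der$feature_class[i] == "sum" && length(den)) {
        stop("sum feature '", der$id[i], "' must have an empty denominator", call. = FALSE)
      }
      if (der$feature_class[i] != "sum" && (!length(num) || !length(den))) {
        stop("ratio feature '", der$id[i], "' needs non-empty numerator and denominator", call. = FALSE)
      }
      if (length(intersect(num, den))) {
        stop("feature '", der$id[i], "' has overlapping numerator and denominator", call. = FALSE)
      }
    }
  }
  invisible(reg)
}

#' Count features per class
#'
#' @param registry A `sh_registry`.
#' @return Named integer vector with counts of `individual`, `sum`,
#'   `sg_ratio` and `enzyme_ratio` features.
#' @export
feature_counts <- function(registry) {
  stopifnot(inherits(registry, "sh_registry"))
  cls <- registry$derived$feature_class
  c(
    individual = nrow(registry$metabolites),
    sum = sum(cls == "sum"),
    sg_ratio = sum(cls == "sg_ratio"),
    enzyme_ratio = sum(cls == "enzyme_ratio")
  )
}

#' Cohort calibration medians and IQRs
#'
#' Metabolite-level medians and interquartile ranges (umol/L) for the two
#' study cohorts, used as the default calibration of the synthetic-cohort
#' generator.
#'
#' @param cohort `"bisc"` (primary) or `"inma"` (replication).
#' @return Tibble with columns `id`, `median`, `iqr`.
#' @export
sh_calibration <- function(cohort = c("bisc", "inma")) {
  cohort <- match.arg(cohort)
  panel <- sh_panel_table()
  if (cohort == "bisc") {
    tibble::tibble(id = panel$id, median = panel$median_bisc, iqr = panel$iqr_bisc)
  } else {
    tibble::tibble(id = panel$id, median = panel$median_inma, iqr = panel$iqr_inma)
  }
}

#' @export
print.sh_registry <- function(x, ...) {
  fc <- feature_counts(x)
  cat("<sh_registry ", x$version, ">\n", sep = "")
  cat("  metabolites: ", fc[["individual"]], "\n", sep = "")
  cat(
    "  derived: ", sum(fc) - fc[["individual"]],
    " (", fc[["sum"]], " sums, ", fc[["sg_ratio"]], " S/G ratios, ",
    fc[["enzyme_ratio"]], " enzyme ratios)\n",
    sep = ""
  )
  invisible(x)
}
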