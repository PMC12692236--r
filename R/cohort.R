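# Lightweight containers. A cohort matrix is a tibble of subjects x
# metabolites with the required columns subject_id, specific_gravity and
# gestational_age_weeks, carrying its unit state ("ng_ml" or "umol_l") and
# correction state ("raw", "sg" or "mom") as attributes so pipeline steps
# can refuse inputs in the wrong state.

SUBJECT_COLS <- c("subject_id", "specific_gravity", "gestational_age_weeks")

#' Construct a cohort concentration matrix
#'
#' @param data Data frame with columns `subject_id`, `specific_gravity`,
#'   `gestational_age_weeks` and one column per metabolite id.
#' @param unit Concentration unit, `"ng_ml"` or `"umol_l"`.
#' @param correction Dilution-correction state: `"raw"`, `"sg"` or `"mom"`.
#' @return A `sh_cohort` tibble.
#' @export
sh_cohort <- function(data, unit = c("ng_ml", "umol_l"), correction = c("raw", "sg", "mom")) {
  unit <- match.arg(unit)
  correction <- match.arg(correction)
  data <- tibble::as_tibble(data)
  miss <- setdiff(SUBJECT_COLS, names(data))
  if (length(miss)) stop("cohort matrix lacks required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  attr(data, "unit") <- unit
  attr(data, "correction") <- correction
  class(data) <- c("sh_cohort", class(data))
  data
}

#' Read a cohort concentration table from CSV/TSV
#'
#' @inheritParams sh_cohort
#' @param path File path; the delimiter is inferred from the extension
#'   (`.tsv` tab, otherwise comma).
#' @return A `sh_cohort` tibble.
#' @export
read_cohort <- function(path, unit = "ng_ml", correction = "raw") {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  sh_cohort(df, unit = unit, correction = correction)
}

#' Write a cohort table to TSV
#'
#' @param cohort A `sh_cohort` or plain data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

cohort_unit <- function(cohort) attr(cohort, "unit") %||% "ng_ml"
cohort_correction <- function(cohort) attr(cohort, "correction") %||% "raw"

metabolite_cols <- function(cohort, registry = NULL) {
  cols <- setdiff(names(cohort), SUBJECT_COLS)
  if (!is.null(registry)) cols <- intersect(cols, registry$metabolites$id)
  cols
}

conc_matrix <- function(cohort, cols = NULL) {
  cols <- cols %||% metabolite_cols(cohort)
  m <- as.matrix(as.data.frame(cohort)[, cols, drop = FALSE])
  rownames(m) <- cohort$subject_id
  storage.mode(m) <- "double"
  m
}

set_conc <- function(cohort, m) {
  for (j in colnames(m)) cohort[[j]] <- unname(m[, j])
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a
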