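## Cohort container, CSV I/O, response-label derivation, summaries.
##
## A cohort is a tibble with one row per patient and fixed lowercase columns
## (patient_id, age, phenotype, rcb, cd4, cd8, foxp3, pd1, ctla4, lag3, tim3).
## Marker columns hold percent-positive cells in [0, 100], one value per
## patient (tissue-image averaging is assumed to have happened upstream of
## this table). RCB is stored canonically as RCB0..RCB3.

cohort_columns <- function() {
  c("patient_id", "age", "phenotype", "rcb", tolower(MARKERS))
}

canonicalize_rcb <- function(x) {
  map <- c(
    "0" = "RCB0", "1" = "RCB1", "2" = "RCB2", "3" = "RCB3",
    "I" = "RCB1", "II" = "RCB2", "III" = "RCB3",
    "RCB0" = "RCB0", "RCB1" = "RCB1", "RCB2" = "RCB2", "RCB3" = "RCB3"
  )
  out <- unname(map[trimws(as.character(x))])
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    abort_nact("nactsig_validation_error",
      sprintf("unrecognized RCB value '%s' in row %d (expected 0/I/II/III or 0-3)",
              as.character(x)[bad], bad))
  }
  out
}

#' Assemble and validate a patient cohort
#'
#' Builds the canonical cohort table from per-patient clinical fields and IHC
#' marker positivities, enforcing the container's invariants: unique patient
#' identifiers, known phenotype and RCB levels, and all seven marker values
#' finite within \[0, 100\] (missing markers are an error, never imputed).
#'
#' @param df A data frame with columns `patient_id`, `age`, `phenotype`,
#'   `rcb`, and the seven lowercase marker columns (`cd4`, `cd8`, `foxp3`,
#'   `pd1`, `ctla4`, `lag3`, `tim3`). `rcb` may use `0/I/II/III`, `0-3`, or
#'   `RCB0-RCB3` notation; it is canonicalized to `RCB0..RCB3`.
#' @return A validated cohort tibble (class `nact_cohort`), row order
#'   preserved.
#' @export
as_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols) > 0) {
    abort_nact("nactsig_missing_column_error",
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(df[cohort_columns()])
  out$patient_id <- as.character(out$patient_id)
  if (anyDuplicated(out$patient_id)) {
    dup <- out$patient_id[duplicated(out$patient_id)][1L]
    abort_nact("nactsig_duplicate_id_error",
      sprintf("duplicated patient_id '%s'", dup))
  }
  out$phenotype <- trimws(as.character(out$phenotype))
  bad_ph <- which(!out$phenotype %in% PHENOTYPES)
  if (length(bad_ph) > 0) {
    abort_nact("nactsig_validation_error",
      sprintf("unknown phenotype '%s' in row %d (expected %s)",
              out$phenotype[bad_ph[1L]], bad_ph[1L],
              paste(PHENOTYPES, collapse = "/")))
  }
  out$rcb <- canonicalize_rcb(out$rcb)
  out$age <- validate_numeric_column(out$age, "age", lower = 0, upper = Inf)
  for (m in tolower(MARKERS)) {
    out[[m]] <- validate_numeric_column(out[[m]], m, lower = 0, upper = 100)
  }
  class(out) <- c("nact_cohort", class(out))
  out
}

validate_numeric_column <- function(x, col, lower, upper) {
  xn <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(xn) | !is.finite(xn))
  if (length(bad) > 0) {
    abort_nact("nactsig_nonnumeric_error",
      sprintf("non-numeric or missing value '%s' in column '%s', row %d",
              as.character(x)[bad[1L]], col, bad[1L]))
  }
  oob <- which(xn < lower | xn > upper)
  if (length(oob) > 0) {
    abort_nact("nactsig_range_error",
      sprintf("value %s in column '%s', row %d outside [%s, %s]",
              format(xn[oob[1L]]), col, oob[1L], format(lower), format(upper)))
  }
  xn
}

#' Read a cohort from CSV
#'
#' Reads the comma-separated, UTF-8, header-required cohort dialect
#' (`patient_id, age, phenotype, rcb, cd4, cd8, foxp3, pd1, ctla4, lag3,
#' tim3`) and validates it with [as_cohort()]. Distinct error conditions name
#' the offending row and column for missing columns
#' (`nactsig_missing_column_error`), non-numeric markers
#' (`nactsig_nonnumeric_error`), out-of-range markers
#' (`nactsig_range_error`), and duplicated ids
#' (`nactsig_duplicate_id_error`).
#'
#' @param path Path to a CSV file.
#' @return A validated cohort tibble, file row order preserved.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    abort_nact("nactsig_io_error", sprintf("cohort file not found: '%s'", path))
  }
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  as_cohort(raw)
}

#' Write a cohort to CSV
#'
#' Serializes a cohort in the same dialect [read_cohort_csv()] reads, at full
#' double precision (17 significant digits), so that a write/read round trip
#' is the identity.
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- as.data.frame(cohort)[cohort_columns()]
  for (col in c("age", tolower(MARKERS))) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Derive binary response labels from RCB class
#'
#' Two dichotomizations are used in the analysis. `pcr_vs_rd` is the modeling
#' dichotomy: pathological complete response (RCB 0) is the negative class 0
#' and residual disease (RCB I-III) the positive class 1. `sens_vs_res` is
#' the deconvolution dichotomy: chemosensitive (RCB 0-I) is 0 and
#' chemoresistant (RCB II-III) is 1.
#'
#' @param cohort A cohort tibble.
#' @param scheme `"pcr_vs_rd"` or `"sens_vs_res"`.
#' @return An integer vector of 0/1 labels aligned to cohort rows.
#' @export
derive_labels <- function(cohort, scheme = c("pcr_vs_rd", "sens_vs_res")) {
  if (length(scheme) == 1L && !scheme %in% c("pcr_vs_rd", "sens_vs_res")) {
    abort_nact("nactsig_config_error",
      sprintf("unknown response scheme '%s'", scheme))
  }
  scheme <- match.arg(scheme)
  positive <- switch(scheme,
    pcr_vs_rd    = c("RCB1", "RCB2", "RCB3"),
    sens_vs_res  = c("RCB2", "RCB3")
  )
  as.integer(cohort$rcb %in% positive)
}

#' Summarize a cohort
#'
#' Counts and percentages per RCB class and per molecular phenotype, plus
#' mean age overall and per RCB class. Percentages are stored at full
#' precision and recompute exactly from the counts; an empty cohort yields
#' zero counts and `NaN` means.
#'
#' @param cohort A cohort tibble.
#' @return A list of class `nact_cohort_summary` with elements `n`,
#'   `rcb_counts`, `rcb_pct`, `phenotype_counts`, `phenotype_pct`,
#'   `mean_age`, `mean_age_by_rcb`.
#' @export
summarize_cohort <- function(cohort) {
  n <- nrow(cohort)
  rcb_counts <- vapply(RCB_CLASSES, function(k) sum(cohort$rcb == k), 0L)
  ph_counts <- vapply(PHENOTYPES, function(k) sum(cohort$phenotype == k), 0L)
  pct <- function(x) if (n == 0) setNames(rep(NaN, length(x)), names(x)) else 100 * x / n
  out <- list(
    n = n,
    rcb_counts = rcb_counts,
    rcb_pct = pct(rcb_counts),
    phenotype_counts = ph_counts,
    phenotype_pct = pct(ph_counts),
    mean_age = if (n == 0) NaN else mean(cohort$age),
    mean_age_by_rcb = vapply(RCB_CLASSES, function(k) {
      idx <- cohort$rcb == k
      if (!any(idx)) NaN else mean(cohort$age[idx])
    }, 0)
  )
  class(out) <- "nact_cohort_summary"
  out
}

#' @export
print.nact_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients (mean age %.1f)\n", x$n, x$mean_age))
  cat("RCB: ", paste(sprintf("%s %d (%.1f%%)", RCB_CLASSES, x$rcb_counts,
                             x$rcb_pct), collapse = ", "), "\n")
  cat("Phenotype: ", paste(sprintf("%s %d (%.1f%%)", PHENOTYPES,
                                   x$phenotype_counts, x$phenotype_pct),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a cohort summary to JSON
#'
#' @param summary A `nact_cohort_summary`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly if written to a file).
#' @export
cohort_summary_json <- function(summary, path = NULL) {
  js <- jsonlite::toJSON(unclass(summary), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
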