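## Composite immune-feature engineering: the 80 candidate features derived
## from the seven IHC markers.

#' Enumerate candidate immune features
#'
#' Produces the canonical ordered feature set over `m` markers and a
#' regulatory subset R: all singles (m), unordered pairwise products
#' (C(m,2), operands in input order), ordered pairwise ratios (m(m-1),
#' numerator/denominator), and the T cell-contextualized forms
#' `(CD8*R)/CD4` and `(CD4*R)/CD8` for each regulatory marker (2|R|). With
#' the default seven markers and five regulatory markers this is
#' 7 + 21 + 42 + 10 = 80 features.
#'
#' Canonical names join operands with `*` and `/`, parenthesizing composite
#' numerators (`"CD8/CD4"`, `"CD4*CD8"`, `"(CD8*CTLA4)/CD4"`), giving stable
#' cross-run joins.
#'
#' @param marker_names Marker vocabulary; must contain CD4 and CD8.
#' @param regulatory_names Subset of `marker_names` excluding CD4/CD8 used
#'   for contextualized features.
#' @return A tibble with `name`, `category`
#'   (single/product/ratio/contextualized), and list-column `operands`.
#' @export
enumerate_features <- function(marker_names = nact_markers(),
                               regulatory_names = nact_regulatory_markers()) {
  stopifnot(length(marker_names) >= 2, !anyDuplicated(marker_names))
  if (!all(c("CD4", "CD8") %in% marker_names)) {
    abort_nact("nactsig_config_error", "marker set must contain CD4 and CD8")
  }
  bad <- setdiff(regulatory_names, setdiff(marker_names, c("CD4", "CD8")))
  if (length(bad) > 0) {
    abort_nact("nactsig_config_error",
      sprintf("regulatory name(s) not usable: %s", paste(bad, collapse = ", ")))
  }
  m <- length(marker_names)
  defs <- list()
  for (mk in marker_names) {
    defs[[length(defs) + 1L]] <- list(name = mk, category = "single",
                                      operands = mk)
  }
  if (m >= 2) {
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      defs[[length(defs) + 1L]] <- list(
        name = paste0(marker_names[i], "*", marker_names[j]),
        category = "product",
        operands = c(marker_names[i], marker_names[j]))
    }
  }
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    defs[[length(defs) + 1L]] <- list(
      name = paste0(marker_names[i], "/", marker_names[j]),
      category = "ratio",
      operands = c(marker_names[i], marker_names[j]))
  }
  for (r in regulatory_names) {
    defs[[length(defs) + 1L]] <- list(
      name = paste0("(CD8*", r, ")/CD4"), category = "contextualized",
      operands = c("CD8", r, "CD4"))
    defs[[length(defs) + 1L]] <- list(
      name = paste0("(CD4*", r, ")/CD8"), category = "contextualized",
      operands = c("CD4", r, "CD8"))
  }
  tibble(
    name = vapply(defs, `[[`, "", "name"),
    category = vapply(defs, `[[`, "", "category"),
    operands = lapply(defs, `[[`, "operands")
  )
}

#' Compute the feature matrix for a cohort
#'
#' Singles are copied; products are `mi * mj`; ratios are
#' `mi / max(mj, epsilon)`; contextualized features are
#' `(mi * r) / max(mj, epsilon)`. The epsilon floor on denominators (default
#' 0.01 percent, about one detectable positive cell in a typical field)
#' keeps every entry finite when a marker is scored as zero-positive; the
#' value used is recorded in the `epsilon` attribute of the result.
#'
#' @param cohort A cohort tibble.
#' @param definitions Feature definitions from [enumerate_features()].
#' @param epsilon Positive denominator floor in percent units.
#' @return A tibble (`patient_id` first, one column per feature), with
#'   attribute `epsilon`; row order matches the cohort.
#' @export
compute_features <- function(cohort, definitions = enumerate_features(),
                             epsilon = 0.01) {
  stopifnot(epsilon > 0)
  mk <- as.matrix(as.data.frame(cohort)[tolower(MARKERS)])
  colnames(mk) <- MARKERS
  cols <- vector("list", nrow(definitions))
  for (i in seq_len(nrow(definitions))) {
    ops <- definitions$operands[[i]]
    if (!all(ops %in% colnames(mk))) {
      abort_nact("nactsig_definition_error",
        sprintf("feature '%s' references unknown marker(s)", definitions$name[i]))
    }
    cols[[i]] <- unname(switch(definitions$category[i],
      single = mk[, ops[1]],
      product = mk[, ops[1]] * mk[, ops[2]],
      ratio = mk[, ops[1]] / pmax(mk[, ops[2]], epsilon),
      contextualized = mk[, ops[1]] * mk[, ops[2]] / pmax(mk[, ops[3]], epsilon),
      abort_nact("nactsig_definition_error",
        sprintf("unknown feature category '%s'", definitions$category[i]))
    ))
  }
  names(cols) <- definitions$name
  out <- dplyr::bind_cols(tibble(patient_id = cohort$patient_id),
                          as_tibble(cols, .name_repair = "minimal"))
  stopifnot(all(vapply(cols, function(v) all(is.finite(v)), TRUE)))
  attr(out, "epsilon") <- epsilon
  out
}

#' Serialize feature definitions to JSON
#'
#' @param definitions Output of [enumerate_features()].
#' @param path Optional file path.
#' @return JSON string (invisibly when written).
#' @export
feature_definitions_json <- function(definitions, path = NULL) {
  js <- jsonlite::toJSON(definitions, auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
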