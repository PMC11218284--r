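#' @keywords internal
"_PACKAGE"

# Canonical column names of a cell table; every other column is a marker score.
CELL_META_COLS <- c("cell_id", "x_um", "y_um", "compartment", "phenotype")

COMPARTMENTS <- c("EPI", "TME")

#' Construct and validate a per-cell table
#'
#' A cell table is a plain data frame with one row per segmented cell:
#' `cell_id`, planar nucleus-centroid coordinates `x_um`/`y_um` in
#' micrometres, a tissue `compartment` (`"EPI"` for the epithelial /
#' tumour-cell compartment, `"TME"` for the stromal compartment), an optional
#' `phenotype` label (filled in by [assign_phenotypes()]), and one integer
#' column per marker holding its 0--3 intensity score.
#'
#' @param cell_id character vector of cell identifiers, unique within a core.
#' @param x_um,y_um finite numeric coordinates in micrometres.
#' @param compartment character vector, each `"EPI"` or `"TME"`.
#' @param scores data frame or named list of integer marker scores in
#'   `{0,1,2,3}`, one element per marker.
#' @param phenotype optional character vector of phenotype labels (`NA` for
#'   unassigned cells).
#' @return validated data frame of class `cell_table`.
#' @export
cell_table <- function(cell_id, x_um, y_um, compartment, scores = NULL,
                       phenotype = NA_character_) {
  df <- data.frame(cell_id = as.character(cell_id),
                   x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                   compartment = as.character(compartment),
                   phenotype = rep_len(as.character(phenotype),
                                       length(cell_id)),
                   stringsAsFactors = FALSE)
  if (!is.null(scores)) {
    scores <- as.data.frame(scores, optional = TRUE)
    stopifnot(nrow(scores) == nrow(df) || nrow(df) == 0L)
    df <- cbind(df, scores)
  }
  validate_cell_table(df)
}

#' @rdname cell_table
#' @param cells data frame to validate.
#' @export
validate_cell_table <- function(cells) {
  stopifnot(is.data.frame(cells))
  missing <- setdiff(setdiff(CELL_META_COLS, "phenotype"), names(cells))
  if (length(missing))
    stop("cell table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (!"phenotype" %in% names(cells)) cells$phenotype <- NA_character_
  bad_xy <- !is.finite(cells$x_um) | !is.finite(cells$y_um)
  if (any(bad_xy))
    stop("non-finite coordinates at row(s): ",
         paste(utils::head(which(bad_xy), 5L), collapse = ", "))
  bad_comp <- !cells$compartment %in% COMPARTMENTS
  if (any(bad_comp))
    stop("unknown compartment value(s): ",
         paste(unique(cells$compartment[bad_comp]), collapse = ", "))
  for (m in marker_names(cells)) {
    s <- cells[[m]]
    if (!is.numeric(s) || any(!is.na(s) & (s != round(s) | s < 0 | s > 3)))
      stop("marker '", m, "' has scores outside {0,1,2,3}")
    cells[[m]] <- as.integer(s)
  }
  class(cells) <- unique(c("cell_table", class(cells)))
  cells
}

#' Marker columns of a cell table
#' @param cells a cell table.
#' @return character vector of marker names.
#' @export
marker_names <- function(cells) setdiff(names(cells), CELL_META_COLS)

#' Construct a tissue-core profile
#'
#' A `core_profile` bundles one TMA core: its cell table, the areas of the
#' two tissue compartments (mm^2, from the segmentation summary), the staining
#' panel it was subjected to, the patient it came from, and a boolean QC flag.
#' Cores with `qc_pass = FALSE` are excluded from every cohort-level
#' computation.
#'
#' @param core_id,patient_id identifiers.
#' @param panel_id one of `"M"`, `"T"`, `"O"` (or any configured panel id).
#' @param cells a [cell_table()].
#' @param area_epi_mm2,area_tme_mm2 compartment areas in mm^2 (`NA` until a
#'   segment summary is attached; must be non-negative otherwise).
#' @param qc_pass logical QC flag.
#' @return object of class `core_profile`.
#' @export
core_profile <- function(core_id, patient_id = NA_character_,
                         panel_id = NA_character_, cells,
                         area_epi_mm2 = NA_real_, area_tme_mm2 = NA_real_,
                         qc_pass = TRUE) {
  cells <- validate_cell_table(cells)
  for (a in c(area_epi_mm2, area_tme_mm2))
    if (!is.na(a) && (!is.numeric(a) || a < 0)) stop("compartment areas must be >= 0")
  structure(list(core_id = as.character(core_id),
                 patient_id = as.character(patient_id),
                 panel_id = as.character(panel_id),
                 cells = cells,
                 area_epi_mm2 = as.numeric(area_epi_mm2),
                 area_tme_mm2 = as.numeric(area_tme_mm2),
                 qc_pass = isTRUE(qc_pass)),
            class = "core_profile")
}

#' @export
print.core_profile <- function(x, ...) {
  cat(sprintf("<core_profile> %s  patient=%s panel=%s  %d cells  EPI=%.3f mm^2 TME=%.3f mm^2  qc_pass=%s\n",
              x$core_id, x$patient_id, x$panel_id, nrow(x$cells),
              x$area_epi_mm2, x$area_tme_mm2, x$qc_pass))
  invisible(x)
}

#' Keep only QC-passing cores
#' @param cores list of [core_profile()] objects.
#' @return filtered list.
#' @export
qc_passing <- function(cores) Filter(function(co) isTRUE(co$qc_pass), cores)

#' Compartment area of a core
#' @param core a [core_profile()].
#' @param compartment `"EPI"` or `"TME"`.
#' @return area in mm^2.
#' @export
compartment_area <- function(core, compartment) {
  compartment <- match.arg(compartment, COMPARTMENTS)
  if (compartment == "EPI") core$area_epi_mm2 else core$area_tme_mm2
}

CLINICAL_LEVELS <- list(
  age_group = c("<65", ">=65"),
  sex = c("Female", "Male"),
  location = c("Right colon", "Left colon", "Rectum"),
  size_group = c("<5", ">=5"),
  t_stage = c("T1", "T2", "T3", "T4"),
  n_stage = c("N0", "N1", "N2"),
  m_stage = c("M0", "M1"),
  ajcc = c("AJCC1", "AJCC2", "AJCC3", "AJCC4"))

#' Validate a clinical table
#'
#' One row per patient with the covariates used throughout the cohort
#' analyses: dichotomised age (`<65` / `>=65`), sex, tumour location,
#' dichotomised maximum diameter (`<5` / `>=5` cm), TNM stages, AJCC (7th
#' edition) stage, TMA array of origin, and overall survival follow-up
#' (`os_months` >= 0, `os_event` in {0,1}).
#'
#' @param clin data frame of patient records.
#' @return validated data frame keyed by `patient_id`.
#' @export
validate_clinical_table <- function(clin) {
  stopifnot(is.data.frame(clin))
  need <- c("patient_id", names(CLINICAL_LEVELS), "array", "os_months", "os_event")
  missing <- setdiff(need, names(clin))
  if (length(missing))
    stop("clinical table is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(clin$patient_id))
    stop("duplicate patient_id in clinical table: ",
         paste(unique(clin$patient_id[duplicated(clin$patient_id)]), collapse = ", "))
  for (v in names(CLINICAL_LEVELS)) {
    bad <- !is.na(clin[[v]]) & !clin[[v]] %in% CLINICAL_LEVELS[[v]]
    if (any(bad))
      stop("clinical field '", v, "' has values outside its vocabulary: ",
           paste(unique(clin[[v]][bad]), collapse = ", "))
  }
  if (!is.numeric(clin$os_months) || any(is.na(clin$os_months)) || any(clin$os_months < 0))
    stop("os_months must be numeric and >= 0")
  if (any(!clin$os_event %in% c(0L, 1L)))
    stop("os_event must be 0 or 1")
  clin$os_event <- as.integer(clin$os_event)
  clin
}
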