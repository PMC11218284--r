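#' inForm-style cell table dialect
#'
#' The exact column naming of an inForm export varies between versions and
#' projects, so it is externalised here. The defaults follow the common
#' "cell_seg_data" convention: one row per cell, a sample name identifying
#' the core, cell positions, a tissue category, and one "<Marker> Score"
#' column per marker.
#'
#' @param microns_per_pixel scale applied when `unit = "pixel"` (0.5 is the
#'   Vectra 20x convention).
#' @param unit unit of the position columns in the file; positions are
#'   converted to micrometres at ingest.
#' @param category_map named character vector mapping tissue-category strings
#'   in the file to `"EPI"` / `"TME"`. Unmapped categories are a hard error.
#' @param col_core,col_cell,col_x,col_y,col_category column names.
#' @param score_suffix suffix identifying marker score columns.
#' @param col_phenotype optional phenotype column (written on export, read
#'   back if present).
#' @return a list of class `cell_dialect`.
#' @export
inform_dialect <- function(microns_per_pixel = 0.5,
                           unit = c("um", "pixel"),
                           category_map = c("EPI" = "EPI", "TME" = "TME",
                                            "Tumor" = "EPI", "epithelium" = "EPI",
                                            "Stroma" = "TME"),
                           col_core = "Sample Name",
                           col_cell = "Cell ID",
                           col_x = "Cell X Position",
                           col_y = "Cell Y Position",
                           col_category = "Tissue Category",
                           score_suffix = " Score",
                           col_phenotype = "Phenotype") {
  structure(list(microns_per_pixel = microns_per_pixel, unit = match.arg(unit),
                 category_map = category_map, col_core = col_core,
                 col_cell = col_cell, col_x = col_x, col_y = col_y,
                 col_category = col_category, score_suffix = score_suffix,
                 col_phenotype = col_phenotype),
            class = "cell_dialect")
}

read_tsv_checked <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' Read an inForm-style per-cell segmentation table
#'
#' Parses a tab-delimited per-cell table into a list of [core_profile()]
#' objects (one per distinct sample name). Compartment areas are unknown at
#' this stage (`NA`) until [attach_segment_summary()] merges the per-core
#' segment summary. Parsing never silently drops rows: a malformed coordinate
#' or an unmapped tissue category raises an error naming the row or value.
#'
#' @param path path to the tab-delimited file.
#' @param dialect an [inform_dialect()].
#' @return named list of [core_profile()] objects.
#' @export
read_cell_table <- function(path, dialect = inform_dialect()) {
  raw <- read_tsv_checked(path)
  need <- c(dialect$col_core, dialect$col_cell, dialect$col_x, dialect$col_y,
            dialect$col_category)
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("cell table '", path, "' is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  x <- suppressWarnings(as.numeric(raw[[dialect$col_x]]))
  y <- suppressWarnings(as.numeric(raw[[dialect$col_y]]))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad))
    stop("non-numeric cell coordinate at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (dialect$unit == "pixel") {
    x <- x * dialect$microns_per_pixel
    y <- y * dialect$microns_per_pixel
  }
  cat_raw <- as.character(raw[[dialect$col_category]])
  unmapped <- setdiff(unique(cat_raw), names(dialect$category_map))
  if (length(unmapped))
    stop("unmapped tissue categor(ies): ", paste(unmapped, collapse = ", "),
         "; extend the dialect's category_map")
  score_cols <- grep(paste0(gsub("([^[:alnum:]])", "\\\\\\1", dialect$score_suffix), "$"),
                     names(raw), value = TRUE)
  markers <- sub(paste0(gsub("([^[:alnum:]])", "\\\\\\1", dialect$score_suffix), "$"),
                 "", score_cols)
  scores <- raw[score_cols]
  names(scores) <- markers
  phen <- if (dialect$col_phenotype %in% names(raw))
    as.character(raw[[dialect$col_phenotype]]) else NA_character_
  cells <- cell_table(cell_id = raw[[dialect$col_cell]], x_um = x, y_um = y,
                      compartment = unname(dialect$category_map[cat_raw]),
                      scores = if (length(markers)) scores else NULL,
                      phenotype = phen)
  core_ids <- as.character(raw[[dialect$col_core]])
  out <- lapply(split(seq_len(nrow(cells)), core_ids), function(i) {
    sub <- cells[i, , drop = FALSE]
    # a combined multi-panel file stores the union of marker columns; a
    # marker never scored on this core belongs to another panel
    for (m in marker_names(sub)) if (all(is.na(sub[[m]]))) sub[[m]] <- NULL
    core_profile(core_id = core_ids[i[1L]], cells = sub)
  })
  out[order(names(out))]
}

#' Write per-cell tables in the inForm-style dialect
#'
#' Inverse of [read_cell_table()]: all cores are written into one
#' tab-delimited file with a deterministic column order, so that
#' read-after-write reproduces the cell tables exactly.
#'
#' @param cores list of [core_profile()] objects.
#' @param path output path.
#' @param dialect an [inform_dialect()] (positions are written in
#'   micrometres; the dialect's unit is ignored on write).
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cores, path, dialect = inform_dialect()) {
  rows <- lapply(cores, function(co) {
    cells <- co$cells
    out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                      a = co$core_id, b = cells$cell_id,
                      c = cells$x_um, d = cells$y_um, e = cells$compartment)
    names(out) <- c(dialect$col_core, dialect$col_cell, dialect$col_x,
                    dialect$col_y, dialect$col_category)
    for (m in marker_names(cells))
      out[[paste0(m, dialect$score_suffix)]] <- cells[[m]]
    out[[dialect$col_phenotype]] <- cells$phenotype
    out
  })
  # cores from different panels carry different marker columns: write the
  # union, leaving markers unscored on a panel blank
  all_cols <- unique(unlist(lapply(rows, names)))
  phen_col <- dialect$col_phenotype
  all_cols <- c(setdiff(all_cols, phen_col), phen_col)
  rows <- lapply(rows, function(d) {
    for (col in setdiff(all_cols, names(d))) d[[col]] <- NA
    d[all_cols]
  })
  combined <- do.call(rbind, rows)
  utils::write.table(combined, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a per-core tissue-segment summary
#'
#' The segment summary ("cell_seg_data_summary" dialect) carries one row per
#' core and compartment with the segmented region area, plus the patient and
#' panel the core belongs to and its QC flag. Pixel areas are converted to
#' mm^2 with the dialect's microns-per-pixel scale.
#'
#' @param path path to the tab-delimited summary.
#' @param dialect an [inform_dialect()] (supplies the core/category column
#'   names and pixel scale).
#' @return data frame with columns `core_id`, `patient_id`, `panel_id`,
#'   `area_epi_mm2`, `area_tme_mm2`, `qc_pass`.
#' @export
read_segment_summary <- function(path, dialect = inform_dialect()) {
  raw <- read_tsv_checked(path)
  need <- c(dialect$col_core, "Patient ID", "Panel", dialect$col_category)
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("segment summary '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  if ("Region Area (square microns)" %in% names(raw)) {
    area_mm2 <- as.numeric(raw[["Region Area (square microns)"]]) / 1e6
  } else if ("Region Area (pixels)" %in% names(raw)) {
    area_mm2 <- as.numeric(raw[["Region Area (pixels)"]]) *
      dialect$microns_per_pixel^2 / 1e6
  } else stop("segment summary has no region-area column")
  if (any(is.na(area_mm2) | area_mm2 < 0))
    stop("segment summary contains invalid region areas")
  cat_raw <- as.character(raw[[dialect$col_category]])
  unmapped <- setdiff(unique(cat_raw), names(dialect$category_map))
  if (length(unmapped))
    stop("unmapped tissue categor(ies) in summary: ", paste(unmapped, collapse = ", "))
  comp <- unname(dialect$category_map[cat_raw])
  qc <- if ("QC Pass" %in% names(raw)) as.logical(raw[["QC Pass"]]) else TRUE
  long <- data.frame(core_id = as.character(raw[[dialect$col_core]]),
                     patient_id = as.character(raw[["Patient ID"]]),
                     panel_id = as.character(raw[["Panel"]]),
                     compartment = comp, area_mm2 = area_mm2, qc_pass = qc,
                     stringsAsFactors = FALSE)
  wide <- do.call(rbind, lapply(split(long, long$core_id), function(d) {
    data.frame(core_id = d$core_id[1L], patient_id = d$patient_id[1L],
               panel_id = d$panel_id[1L],
               area_epi_mm2 = sum(d$area_mm2[d$compartment == "EPI"]),
               area_tme_mm2 = sum(d$area_mm2[d$compartment == "TME"]),
               qc_pass = all(d$qc_pass), stringsAsFactors = FALSE)
  }))
  rownames(wide) <- NULL
  wide[order(wide$core_id), ]
}

#' @rdname read_segment_summary
#' @param cores list of [core_profile()] objects to summarise.
#' @export
write_segment_summary <- function(cores, path, dialect = inform_dialect()) {
  rows <- lapply(cores, function(co) {
    out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                      a = co$core_id, b = co$patient_id, c = co$panel_id,
                      d = c("EPI", "TME"),
                      e = c(co$area_epi_mm2, co$area_tme_mm2) * 1e6,
                      f = co$qc_pass)
    names(out) <- c(dialect$col_core, "Patient ID", "Panel",
                    dialect$col_category, "Region Area (square microns)",
                    "QC Pass")
    out
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Attach segment-summary metadata to cores
#'
#' Fills in patient, panel, compartment areas and the QC flag from a
#' [read_segment_summary()] table. Cores without a summary row are an error
#' (areas would be undefined downstream).
#'
#' @param cores named list of [core_profile()] objects.
#' @param summary data frame from [read_segment_summary()].
#' @return list of completed [core_profile()] objects.
#' @export
attach_segment_summary <- function(cores, summary) {
  idx <- match(vapply(cores, `[[`, "", "core_id"), summary$core_id)
  if (anyNA(idx))
    stop("no segment-summary row for core(s): ",
         paste(vapply(cores[is.na(idx)], `[[`, "", "core_id"), collapse = ", "))
  Map(function(co, i) {
    co$patient_id <- summary$patient_id[i]
    co$panel_id <- summary$panel_id[i]
    co$area_epi_mm2 <- summary$area_epi_mm2[i]
    co$area_tme_mm2 <- summary$area_tme_mm2[i]
    co$qc_pass <- summary$qc_pass[i]
    co
  }, cores, idx)
}

#' Read / write the per-patient clinical table
#'
#' Tab- or comma-delimited (inferred from the extension), one row per
#' patient; validated against the controlled vocabularies of
#' [validate_clinical_table()]. Duplicate patient ids and unparsable survival
#' fields are errors.
#'
#' @param path file path (`.csv` for comma-delimited, anything else tab).
#' @return validated clinical data frame.
#' @export
read_clinical_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  os <- suppressWarnings(as.numeric(raw$os_months))
  if (any(is.na(os)))
    stop("unparsable os_months at row(s): ",
         paste(utils::head(which(is.na(os)), 5L), collapse = ", "))
  raw$os_months <- os
  validate_clinical_table(raw)
}

#' @rdname read_clinical_table
#' @param clin validated clinical data frame.
#' @export
write_clinical_table <- function(clin, path) {
  clin <- validate_clinical_table(clin)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(clin, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a set of result tables with a manifest
#'
#' Writes each table as TSV with its columns in their given (deterministic)
#' order and records every file in a JSON manifest, so a re-run with the same
#' inputs yields byte-identical output.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if absent).
#' @return data frame manifest (file, rows, cols), invisibly also written to
#'   `manifest.json`.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  manifest <- do.call(rbind, lapply(names(tables), function(nm) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    data.frame(file = basename(f), rows = nrow(tables[[nm]]),
               cols = ncol(tables[[nm]]), stringsAsFactors = FALSE)
  }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
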