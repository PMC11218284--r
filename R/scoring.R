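#' H-score of a marker over a cell population
#'
#' The H-score summarises 0--3 staining intensity scores as
#' `100 * (1*p1 + 2*p2 + 3*p3)`, where `p_k` is the proportion of cells at
#' score level `k`; it ranges from 0 (all negative) to 300 (all score 3).
#'
#' @param cells a [cell_table()] or [core_profile()].
#' @param marker marker to score.
#' @param compartment optional `"EPI"` or `"TME"` filter.
#' @return list of class `h_score`: `marker`, `compartment`, `n`,
#'   proportions `p0..p3`, `h_score`.
#' @export
h_score <- function(cells, marker, compartment = NULL) {
  if (inherits(cells, "core_profile")) cells <- cells$cells
  if (!marker %in% marker_names(cells))
    stop("marker '", marker, "' is not scored on this cell table")
  if (!is.null(compartment)) {
    compartment <- match.arg(compartment, COMPARTMENTS)
    cells <- cells[cells$compartment == compartment, , drop = FALSE]
  }
  if (nrow(cells) == 0L)
    stop("H-score undefined: no cells after filtering (marker '", marker, "')")
  if (anyNA(cells[[marker]]))
    stop("marker '", marker, "' has unscored cells; H-score undefined")
  p <- as.numeric(table(factor(cells[[marker]], levels = 0:3))) / nrow(cells)
  structure(list(marker = marker, compartment = compartment, n = nrow(cells),
                 p0 = p[1L], p1 = p[2L], p2 = p[3L], p3 = p[4L],
                 h_score = 100 * (1 * p[2L] + 2 * p[3L] + 3 * p[4L])),
            class = "h_score")
}

#' @export
print.h_score <- function(x, ...) {
  cat(sprintf("H-score[%s%s] = %.1f  (n=%d; p0..p3 = %.2f %.2f %.2f %.2f)\n",
              x$marker, if (is.null(x$compartment)) "" else paste0(", ", x$compartment),
              x$h_score, x$n, x$p0, x$p1, x$p2, x$p3))
  invisible(x)
}

#' Cell density in a tissue compartment
#'
#' Number of qualifying cells per mm^2 of the compartment, using that
#' compartment's own segmented area. `target` is either an assigned
#' phenotype label or a marker name (counted as marker-positive cells at the
#' given threshold).
#'
#' @param core a [core_profile()] with a known area for `compartment`.
#' @param target phenotype label or marker name.
#' @param compartment `"EPI"` or `"TME"`.
#' @param threshold positivity threshold when `target` is a marker.
#' @return cells per mm^2.
#' @export
density_per_mm2 <- function(core, target, compartment, threshold = 1L) {
  compartment <- match.arg(compartment, COMPARTMENTS)
  cells <- core$cells
  in_comp <- cells$compartment == compartment
  n <- if (target %in% marker_names(cells)) {
    sum(is_positive(cells, target, threshold) & in_comp)
  } else {
    sum(!is.na(cells$phenotype) & cells$phenotype == target & in_comp)
  }
  area <- compartment_area(core, compartment)
  if (is.na(area)) stop("compartment area unknown for core ", core$core_id)
  if (area == 0) {
    if (n > 0) stop("zero ", compartment, " area with ", n,
                    " counted cells in core ", core$core_id)
    return(0)
  }
  n / area
}

#' Tumour purity of a core
#'
#' Fraction of the core's cells lying in the epithelial (tumour-cell)
#' compartment — the mIHC analogue of molecular tumour-purity estimates.
#'
#' @param core a [core_profile()] with at least one cell.
#' @return list of class `purity_result`: `core_id`, `panel_id`, `n_epi`,
#'   `n_total`, `purity` in \[0,1\].
#' @export
tumor_purity <- function(core) {
  n <- nrow(core$cells)
  if (n == 0L) stop("tumour purity undefined for empty core ", core$core_id)
  n_epi <- sum(core$cells$compartment == "EPI")
  structure(list(core_id = core$core_id, panel_id = core$panel_id,
                 n_epi = n_epi, n_total = n, purity = n_epi / n),
            class = "purity_result")
}

#' Mean cell count per sample
#'
#' Cohort total divided by the number of samples, reported to one decimal
#' (the convention used for per-sample abundance summaries).
#'
#' @param total_count total cells identified across the cohort.
#' @param n_samples number of samples (> 0).
#' @return mean count per sample, rounded to one decimal.
#' @export
mean_count_per_sample <- function(total_count, n_samples) {
  stopifnot(total_count >= 0)
  if (n_samples <= 0) stop("n_samples must be > 0")
  round(total_count / n_samples, 1L)
}

#' Patient-by-(compartment, phenotype) density matrix
#'
#' Assigns phenotypes on every QC-passing core, pools cores of the same
#' patient and panel (summing counts and compartment areas), and returns the
#' matrix of positive-cell densities (cells/mm^2) with one row per patient
#' and one `<compartment>.<phenotype>` column per panel phenotype. Pan
#' tallies (CD3T) are included; the epithelial-only cycling-cancer phenotype
#' contributes its EPI column only.
#'
#' @param cores list of [core_profile()] objects.
#' @param panels named list of [panel_config()]s keyed by panel id
#'   (default [default_panels()]).
#' @param compartments compartments to include as column blocks.
#' @return numeric data frame, rownames = patient ids, plus attribute
#'   `"n_cores"` (cores pooled per patient).
#' @export
build_density_matrix <- function(cores, panels = default_panels(),
                                 compartments = COMPARTMENTS) {
  cores <- qc_passing(cores)
  if (!length(cores)) stop("no QC-passing cores")
  epi_only <- "CyclingCancer"
  col_df <- do.call(rbind, lapply(names(panels), function(pid) {
    phens <- panel_phenotypes(panels[[pid]])
    do.call(rbind, lapply(phens, function(ph) {
      comps <- if (ph %in% epi_only) intersect("EPI", compartments) else compartments
      if (!length(comps)) return(NULL)
      data.frame(col = paste0(comps, ".", ph), panel = pid, compartment = comps,
                 phenotype = ph, stringsAsFactors = FALSE)
    }))
  }))
  cols <- col_df$col
  patients <- sort(unique(vapply(cores, `[[`, "", "patient_id")))
  counts <- matrix(0, length(patients), length(cols),
                   dimnames = list(patients, cols))
  # pooled compartment area per (patient, panel, compartment); a phenotype's
  # density uses the area of the panel whose cores it was counted on
  area_key <- function(pid, panel, comp) paste(pid, panel, comp, sep = "\r")
  areas <- new.env(parent = emptyenv())
  for (co in cores) {
    pid <- co$patient_id
    panel <- panels[[co$panel_id]]
    if (is.null(panel)) stop("no panel config for panel id '", co$panel_id, "'")
    pc <- phenotype_counts(co, panel)
    for (comp in compartments) {
      a <- compartment_area(co, comp)
      if (is.na(a)) stop("compartment area unknown for core ", co$core_id)
      k <- area_key(pid, co$panel_id, comp)
      assign(k, (if (exists(k, envir = areas)) get(k, envir = areas) else 0) + a,
             envir = areas)
      sub <- pc[pc$compartment == comp & pc$phenotype != "UNASSIGNED", ]
      key <- paste0(comp, ".", sub$phenotype)
      keep <- key %in% cols
      counts[pid, key[keep]] <- counts[pid, key[keep]] + sub$n[keep]
    }
  }
  dens <- matrix(NA_real_, length(patients), length(cols),
                 dimnames = list(patients, cols))
  for (j in seq_along(cols)) {
    for (pid in patients) {
      k <- area_key(pid, col_df$panel[j], col_df$compartment[j])
      if (!exists(k, envir = areas)) next  # patient has no QC-passing core for this panel
      a <- get(k, envir = areas)
      n <- counts[pid, j]
      if (a == 0) {
        if (n > 0) stop("zero ", col_df$compartment[j], " area with counted cells: patient ",
                        pid, ", panel ", col_df$panel[j])
        dens[pid, j] <- 0
      } else dens[pid, j] <- n / a
    }
  }
  out <- as.data.frame(dens)
  attr(out, "n_cores") <- table(vapply(cores, `[[`, "", "patient_id"))
  out
}
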