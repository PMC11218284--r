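# Blockwise vectorised nearest-neighbour: for each query point the minimum
# Euclidean distance to the reference set. Exact (no grid approximation);
# blocks bound the size of the intermediate cross-distance matrix.
nn_min_dist <- function(qx, qy, rx, ry, block = 2048L) {
  nq <- length(qx)
  if (length(rx) == 0L) return(rep(NA_real_, nq))
  if (nq == 0L) return(numeric(0))
  out <- numeric(nq)
  for (start in seq(1L, nq, by = block)) {
    idx <- start:min(start + block - 1L, nq)
    dx <- outer(qx[idx], rx, "-")
    dy <- outer(qy[idx], ry, "-")
    d2 <- dx * dx + dy * dy
    out[idx] <- sqrt(do.call(pmin, as.data.frame(d2)))
  }
  out
}

DEFAULT_RADII <- c(10, 20, 30)

radius_bin_labels <- function(radii = DEFAULT_RADII) {
  lo <- c(0, radii)
  hi <- c(radii, Inf)
  paste0("(", lo, ",", ifelse(is.finite(hi), hi, "Inf"), "]")
}

# Half-open (a,b] bins on the printed thresholds; a coincident cell
# (distance 0) falls in the innermost bin.
assign_radius_bin <- function(d, radii = DEFAULT_RADII) {
  cut(d, breaks = c(0, radii, Inf), labels = radius_bin_labels(radii),
      include.lowest = TRUE, right = TRUE)
}

#' Tumour-cell reference set of a core
#'
#' The segmentation proxy: cells in the epithelial compartment are
#' considered tumour cells. `"literal"` takes every EPI cell; `"exclude_immune"` drops
#' EPI cells that carry an assigned immune phenotype.
#'
#' @param core a [core_profile()].
#' @param tumor_mode `"literal"` (default) or `"exclude_immune"`.
#' @return logical vector over the core's cells.
#' @export
tumor_cell_set <- function(core, tumor_mode = c("literal", "exclude_immune")) {
  tumor_mode <- match.arg(tumor_mode)
  cells <- core$cells
  is_epi <- cells$compartment == "EPI"
  if (tumor_mode == "literal") return(is_epi)
  immune <- !is.na(cells$phenotype) &
    !cells$phenotype %in% c("UNASSIGNED", "CyclingCancer", "Tumor")
  is_epi & !immune
}

immune_cell_set <- function(cells) {
  !is.na(cells$phenotype) &
    !cells$phenotype %in% c("UNASSIGNED", "CyclingCancer", "Tumor")
}

#' Nearest distance from each immune cell to a tumour cell
#'
#' Exact Euclidean nucleus-centroid distance from every phenotype-assigned
#' immune cell to its closest tumour cell, with its half-open radius bin.
#' Immune cells inside the epithelial compartment are treated like any
#' other. If the core contains no tumour cells all distances are `NA`
#' (flagged missing, not zero).
#'
#' @param core a [core_profile()] with phenotypes assigned.
#' @param radii increasing radius thresholds (micrometres) for binning.
#' @param tumor_mode see [tumor_cell_set()].
#' @return data frame of class `distance_table`: `cell_id`, `phenotype`,
#'   `distance_um`, `radius_bin`; attribute `"no_tumor"` is `TRUE` when the
#'   core had no tumour cells.
#' @export
nearest_tumor_distance <- function(core, radii = DEFAULT_RADII,
                                   tumor_mode = c("literal", "exclude_immune")) {
  stopifnot(all(diff(c(0, radii)) > 0))
  cells <- core$cells
  tset <- tumor_cell_set(core, tumor_mode)
  iset <- immune_cell_set(cells)
  d <- nn_min_dist(cells$x_um[iset], cells$y_um[iset],
                   cells$x_um[tset], cells$y_um[tset])
  # an immune cell lying in the EPI compartment is part of the literal
  # tumour set; its distance is to the nearest *other* tumour cell
  self <- which(iset & tset)
  if (length(self) && sum(tset) >= 2L) {
    t_idx <- which(tset)
    pos <- match(self, which(iset))
    for (k in seq_along(self)) {
      i <- self[k]
      others <- setdiff(t_idx, i)
      d[pos[k]] <- min(sqrt((cells$x_um[others] - cells$x_um[i])^2 +
                              (cells$y_um[others] - cells$y_um[i])^2))
    }
  } else if (length(self) && sum(tset) < 2L) {
    d[match(self, which(iset))] <- NA_real_
  }
  out <- data.frame(cell_id = cells$cell_id[iset],
                    phenotype = cells$phenotype[iset],
                    distance_um = d, stringsAsFactors = FALSE)
  out$radius_bin <- assign_radius_bin(out$distance_um, radii)
  structure(out, no_tumor = sum(tset) == 0L, radii = radii,
            class = c("distance_table", "data.frame"))
}

#' Effective immune cells within a radius
#'
#' Counts the cells of a phenotype that have at least one tumour cell within
#' `radius` micrometres ("effective" immune cells). Computed directly from
#' pairwise squared distances, independently of
#' [nearest_tumor_distance()] (the two agree by definition).
#'
#' @param core a [core_profile()] with phenotypes assigned.
#' @param phenotype phenotype label to count.
#' @param radius positive radius in micrometres (inclusive).
#' @param tumor_mode see [tumor_cell_set()].
#' @return integer count (`NA` if the core has no tumour cells).
#' @export
count_within <- function(core, phenotype, radius,
                         tumor_mode = c("literal", "exclude_immune")) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  cells <- core$cells
  sel <- !is.na(cells$phenotype) & cells$phenotype == phenotype
  tset <- tumor_cell_set(core, tumor_mode)
  if (!sum(tset)) return(NA_integer_)
  if (!sum(sel)) return(0L)
  r2 <- radius^2
  t_idx <- which(tset)
  hits <- vapply(which(sel), function(i) {
    others <- t_idx[t_idx != i]  # a cell is never its own tumour neighbour
    any((cells$x_um[others] - cells$x_um[i])^2 +
          (cells$y_um[others] - cells$y_um[i])^2 <= r2)
  }, logical(1L))
  sum(hits)
}

#' Bin effective cells by distance to the nearest tumour cell
#'
#' Partitions a core's immune cells into the half-open radius bins
#' (0,10], (10,20], (20,30], (30,Inf) (for the default thresholds) by
#' phenotype; bins sum to the phenotype total whenever the core has tumour
#' cells.
#'
#' @param distance_table result of [nearest_tumor_distance()].
#' @return data frame: `phenotype`, one column per bin, `total`.
#' @export
bin_effective_cells <- function(distance_table) {
  radii <- attr(distance_table, "radii") %||% DEFAULT_RADII
  labs <- radius_bin_labels(radii)
  phens <- sort(unique(distance_table$phenotype))
  tab <- table(factor(distance_table$phenotype, levels = phens),
               factor(distance_table$radius_bin, levels = labs))
  out <- data.frame(phenotype = phens, stringsAsFactors = FALSE)
  for (l in labs) out[[l]] <- as.integer(tab[, l])
  out$total <- as.integer(rowSums(tab) +
                            tapply(is.na(distance_table$radius_bin),
                                   factor(distance_table$phenotype, levels = phens),
                                   sum))
  out
}

#' Patient-level effective-cell count matrix
#'
#' For every patient and phenotype: the number of immune cells with at least
#' one tumour cell within each radius threshold (cumulative `within_<r>`
#' columns), the `beyond_<rmax>` remainder, and the phenotype total. Counts
#' are pooled over the patient's QC-passing cores; cores without tumour
#' cells contribute no distances.
#'
#' @param cores list of [core_profile()] objects with phenotypes assigned.
#' @param radii increasing radius thresholds in micrometres.
#' @param tumor_mode see [tumor_cell_set()].
#' @return data frame: `patient_id`, `phenotype`, `within_<r>`...,
#'   `beyond_<rmax>`, `total`.
#' @export
effective_count_matrix <- function(cores, radii = DEFAULT_RADII,
                                   tumor_mode = c("literal", "exclude_immune")) {
  tumor_mode <- match.arg(tumor_mode)
  cores <- qc_passing(cores)
  rows <- lapply(cores, function(co) {
    dt <- nearest_tumor_distance(co, radii, tumor_mode)
    if (attr(dt, "no_tumor") || nrow(dt) == 0L) return(NULL)
    cbind(patient_id = co$patient_id, dt, stringsAsFactors = FALSE)
  })
  all_d <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(all_d) || nrow(all_d) == 0L)
    return(data.frame(patient_id = character(), phenotype = character()))
  key <- interaction(all_d$patient_id, all_d$phenotype, drop = TRUE)
  out <- do.call(rbind, lapply(split(all_d, key), function(d) {
    row <- data.frame(patient_id = d$patient_id[1L], phenotype = d$phenotype[1L],
                      stringsAsFactors = FALSE)
    for (r in radii) row[[paste0("within_", r)]] <- sum(d$distance_um <= r)
    row[[paste0("beyond_", max(radii))]] <- sum(d$distance_um > max(radii))
    row$total <- nrow(d)
    row
  }))
  rownames(out) <- NULL
  out[order(out$patient_id, out$phenotype), ]
}

#' Cohort summary of median nearest-tumour distances
#'
#' Per core, the median nearest-tumour distance of each phenotype; the
#' cohort summary is the distribution of these per-core medians (each tissue
#' core contributes one value), reported as its median with the number of
#' contributing cores. Phenotypes absent from a core are omitted from that
#' core's summary.
#'
#' @param cores list of [core_profile()] objects with phenotypes assigned.
#' @param tumor_mode see [tumor_cell_set()].
#' @return list: `per_core` (core_id, phenotype, median_um, n_cells) and
#'   `cohort` (phenotype, median_of_medians_um, n_cores).
#' @export
median_distance_summary <- function(cores, tumor_mode = c("literal", "exclude_immune")) {
  tumor_mode <- match.arg(tumor_mode)
  cores <- qc_passing(cores)
  per_core <- do.call(rbind, lapply(cores, function(co) {
    dt <- nearest_tumor_distance(co, tumor_mode = tumor_mode)
    if (attr(dt, "no_tumor") || nrow(dt) == 0L) return(NULL)
    med <- tapply(dt$distance_um, dt$phenotype, stats::median)
    data.frame(core_id = co$core_id, phenotype = names(med),
               median_um = as.numeric(med),
               n_cells = as.integer(table(dt$phenotype)[names(med)]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_core))
    return(list(per_core = data.frame(), cohort = data.frame()))
  rownames(per_core) <- NULL
  cohort <- do.call(rbind, lapply(split(per_core, per_core$phenotype), function(d)
    data.frame(phenotype = d$phenotype[1L],
               median_of_medians_um = stats::median(d$median_um),
               n_cores = nrow(d), stringsAsFactors = FALSE)))
  rownames(cohort) <- NULL
  list(per_core = per_core, cohort = cohort[order(cohort$median_of_medians_um), ])
}
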