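# Small in-code fixtures shared across the suite.

# One-call cell table: scores given as a named list of equal-length vectors.
make_cells <- function(x, y, compartment, scores = NULL, phenotype = NA_character_,
                       id_prefix = "c") {
  cell_table(cell_id = sprintf("%s%03d", id_prefix, seq_along(x)),
             x_um = x, y_um = y, compartment = compartment,
             scores = scores, phenotype = phenotype)
}

make_core <- function(cells, core_id = "core1", patient_id = "P1",
                      panel_id = "T", area_epi = 0.2, area_tme = 0.8,
                      qc_pass = TRUE) {
  core_profile(core_id, patient_id, panel_id, cells,
               area_epi_mm2 = area_epi, area_tme_mm2 = area_tme,
               qc_pass = qc_pass)
}

# A single T-panel cell with the given marker scores, for gating examples.
gate_one <- function(..., compartment = "TME", panel = default_panels()$T) {
  scores <- list(...)
  for (m in setdiff(panel$markers, names(scores))) scores[[m]] <- 0L
  cells <- make_cells(0, 0, compartment, scores = scores)
  assign_phenotypes(cells, panel)$phenotype
}

# Independent brute-force nearest-neighbour oracle: plain per-query loop.
brute_nn <- function(qx, qy, rx, ry) {
  vapply(seq_along(qx), function(i)
    min(sqrt((rx - qx[i])^2 + (ry - qy[i])^2)), numeric(1L))
}

# Random core: uniform points in a square, random compartments/phenotypes.
random_core <- function(n_immune = 60, n_tumor = 80, side = 500,
                        phenotypes = c("CD8T", "Treg", "B"),
                        immune_in_epi = 0.1) {
  n <- n_immune + n_tumor
  comp <- c(sample(c("EPI", "TME"), n_immune, TRUE,
                   prob = c(immune_in_epi, 1 - immune_in_epi)),
            rep("EPI", n_tumor))
  phen <- c(sample(phenotypes, n_immune, TRUE), rep("UNASSIGNED", n_tumor))
  cells <- make_cells(runif(n, 0, side), runif(n, 0, side), comp,
                      phenotype = phen)
  make_core(cells)
}
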