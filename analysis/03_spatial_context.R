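#!/usr/bin/env Rscript
# Spatial context of the gated cohort: every immune cell's nearest distance
# to a tumour cell (epithelial-compartment cells), the cohort distribution
# of per-core median distances by phenotype, radius-binned effective-cell
# counts, and the patient-level effective count matrix at 10/20/30 um.

library(immunocontext)

coh <- read_cohort("results/cohort")
cores <- apply_gating(coh$cores)

md <- median_distance_summary(cores)
message("cohort median of per-core median nearest-tumour distances (um):")
message(paste(sprintf("  %s=%.1f", md$cohort$phenotype,
                      md$cohort$median_of_medians_um), collapse = ""))

bins <- do.call(rbind, lapply(qc_passing(cores), function(co) {
  dt <- nearest_tumor_distance(co)
  if (attr(dt, "no_tumor") || !nrow(dt)) return(NULL)
  cbind(core_id = co$core_id, bin_effective_cells(dt))
}))

lab <- c("(0,10]", "(10,20]", "(20,30]", "(30,Inf]")
cohort_bins <- aggregate(bins[lab], list(phenotype = bins$phenotype), sum)
cohort_bins$pct_within_20 <- round(100 * (cohort_bins[["(0,10]"]] + cohort_bins[["(10,20]"]]) /
                                     rowSums(cohort_bins[lab]), 2)
message("share of cells with a tumour cell within 20 um, by phenotype:")
message(paste(sprintf("  %s=%.1f%%", cohort_bins$phenotype,
                      cohort_bins$pct_within_20), collapse = ""))

ec <- effective_count_matrix(cores)

write_results(list(median_distances_per_core = md$per_core,
                   median_distances_cohort = md$cohort,
                   radius_bins_per_core = bins,
                   radius_bins_cohort = cohort_bins,
                   effective_counts = ec),
              "results/spatial")
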