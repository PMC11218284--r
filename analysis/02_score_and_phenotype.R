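#!/usr/bin/env Rscript
# Ingests the simulated cohort from disk, assigns the 14 phenotypes by
# negative-screening gating, and computes the marker-level and cell-level
# quantifications: per-core H-scores by compartment, tumour purity (with its
# cross-panel consistency), per-core phenotype counts, and the patient x
# (compartment, phenotype) density matrix.

library(immunocontext)

coh <- read_cohort("results/cohort")
cores <- apply_gating(coh$cores)
panels <- default_panels()

hs <- do.call(rbind, lapply(qc_passing(cores), function(co) {
  do.call(rbind, lapply(marker_names(co$cells), function(m) {
    do.call(rbind, lapply(c("EPI", "TME"), function(comp) {
      if (!any(co$cells$compartment == comp)) return(NULL)
      h <- h_score(co, m, comp)
      data.frame(core_id = co$core_id, panel_id = co$panel_id, marker = m,
                 compartment = comp, n = h$n, h_score = h$h_score)
    }))
  }))
}))

pur <- do.call(rbind, lapply(qc_passing(cores), function(co) {
  p <- tumor_purity(co)
  data.frame(core_id = p$core_id, patient_id = co$patient_id,
             panel_id = p$panel_id, purity = p$purity)
}))
pw <- reshape(pur[c("patient_id", "panel_id", "purity")],
              idvar = "patient_id", timevar = "panel_id", direction = "wide")
cc <- cor(pw[-1], use = "pairwise.complete.obs")
message(sprintf("cross-panel purity correlations: M-T %.3f, M-O %.3f, T-O %.3f",
                cc["purity.M", "purity.T"], cc["purity.M", "purity.O"],
                cc["purity.T", "purity.O"]))

counts <- do.call(rbind, lapply(qc_passing(cores), function(co)
  cbind(core_id = co$core_id,
        phenotype_counts(co, panels[[co$panel_id]]))))

dm <- build_density_matrix(cores, panels)
b_total <- sum(counts$n[counts$phenotype == "B"])
b_cores <- length(unique(counts$core_id[grepl("_O$", counts$core_id)]))
message(sprintf("B cells: %d across %d O-panel cores, mean %.1f per sample",
                b_total, b_cores, mean_count_per_sample(b_total, b_cores)))

# paired EPI-vs-TME infiltration comparison per phenotype, over patients
# whose panel core has both compartments measured
phens <- sub("^EPI\\.", "", grep("^EPI\\.", colnames(dm), value = TRUE))
paired <- do.call(rbind, lapply(setdiff(phens, "CyclingCancer"), function(ph) {
  e <- dm[[paste0("EPI.", ph)]]; t <- dm[[paste0("TME.", ph)]]
  ok <- !is.na(e) & !is.na(t)
  p <- rank_tests(c(e[ok], t[ok]), rep(c("EPI", "TME"), each = sum(ok)),
                  paired = TRUE)$p
  data.frame(phenotype = ph, n = sum(ok), median_epi = median(e[ok]),
             median_tme = median(t[ok]), p_paired_wilcoxon = p)
}))
message("phenotypes with higher epithelial than stromal density (paired Wilcoxon p<0.05):")
hi_epi <- paired[paired$median_epi > paired$median_tme & paired$p_paired_wilcoxon < 0.05, ]
message(paste(sprintf("  %s (EPI %.0f vs TME %.0f /mm2)", hi_epi$phenotype,
                      hi_epi$median_epi, hi_epi$median_tme), collapse = ""))

write_results(list(hscore = hs, purity = pur, counts = counts,
                   compartment_paired = paired,
                   density = cbind(patient_id = rownames(dm), dm)),
              "results/scoring")
message("median epithelial H-score by marker (QC-passing cores):")
agg <- aggregate(h_score ~ marker, hs[hs$compartment == "EPI", ], median)
message(paste(sprintf("  %s=%.0f", agg$marker, agg$h_score), collapse = ""))
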