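#!/usr/bin/env Rscript
# Unsupervised immune subtyping: Ward (ward.D2) hierarchical clustering of
# z-scored patient densities with silhouette-guided cluster number,
# phenotype-phenotype correlation structure, and differential densities
# between the most- and least-infiltrated subtypes.

library(immunocontext)

dm_file <- read.delim("results/scoring/density.tsv", check.names = FALSE)
dm <- as.matrix(dm_file[-1])
rownames(dm) <- dm_file$patient_id

# complete-case patients: those whose cores passed QC on all three panels
complete <- rowSums(is.na(dm)) == 0
message(sprintf("%d of %d patients have all three panels QC-passing", sum(complete), nrow(dm)))
dmc <- dm[complete, ]

sub <- cluster_patients(dmc, k_range = 2:6)
print(sub)
print(sub$diagnostics)

cm <- phenotype_correlation(dmc)
# report the strongest co-infiltration pairs
ut <- which(upper.tri(cm), arr.ind = TRUE)
ord <- order(-cm[ut])
top <- head(data.frame(a = rownames(cm)[ut[ord, 1]], b = colnames(cm)[ut[ord, 2]],
                       rho = cm[ut][ord]), 5)
message("strongest phenotype correlations (Spearman):")
message(paste(sprintf("  %s~%s rho=%.2f", top$a, top$b, top$rho), collapse = "\n"))

# high- vs low-infiltration subtype, ranked by mean z-scored density
grp_score <- tapply(rowMeans(scale(dmc)), sub$labels, mean)
hi <- names(which.max(grp_score)); lo <- names(which.min(grp_score))
dd <- differential_densities(dmc, names(sub$labels)[sub$labels == hi],
                             names(sub$labels)[sub$labels == lo])
message(sprintf("differential %s vs %s: %d phenotypes pass |log2FC|>1 & p<0.05",
                hi, lo, sum(dd$significant)))

write_results(list(subtypes = data.frame(patient_id = names(sub$labels),
                                         subtype = unname(sub$labels)),
                   diagnostics = sub$diagnostics,
                   correlation = cbind(phenotype = rownames(cm), as.data.frame(cm)),
                   differential = dd),
              "results/subtypes")
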