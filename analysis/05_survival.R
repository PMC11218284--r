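#!/usr/bin/env Rscript
# Outcome analyses: baseline clinical-characteristics tests between the two
# TMA arrays, Kaplan-Meier / log-rank by immune subtype, univariate and
# clinically adjusted Cox models of every density column (median split), and
# distance-stratified prognosis of T-lineage effective cells.

library(immunocontext)

coh <- read_cohort("results/cohort")
clin <- coh$clinical
cores <- apply_gating(coh$cores)

## baseline characteristics by array (chi-squared, Yates for 2x2) ----------
base_vars <- c("age_group", "sex", "size_group", "n_stage", "m_stage",
               "ajcc", "os_event")
clin_tests <- do.call(rbind, lapply(base_vars, function(v) {
  tab <- table(clin[[v]], clin$array)
  res <- tryCatch(contingency_test(tab), error = function(e) NULL)
  if (is.null(res)) return(NULL)
  data.frame(variable = v, statistic = res$statistic, df = res$df,
             p = res$p, yates = res$yates)
}))
message("baseline tests by array:")
message(paste(sprintf("  %s p=%.3f", clin_tests$variable, clin_tests$p), collapse = ""))

## subtype survival ----------------------------------------------------------
sub <- read.delim("results/subtypes/subtypes.tsv")
idx <- match(sub$patient_id, clin$patient_id)
km <- km_logrank(clin$os_months[idx], clin$os_event[idx], sub$subtype)
message(sprintf("subtype log-rank: chisq=%.2f on %d df, p=%.4g", km$chisq, km$df, km$p))

## density forest: median split, univariate and clinically adjusted ---------
dm_file <- read.delim("results/scoring/density.tsv", check.names = FALSE)
dm <- as.matrix(dm_file[-1]); rownames(dm) <- dm_file$patient_id
adjusters <- data.frame(age_group = clin$age_group, sex = clin$sex,
                        t_stage = clin$t_stage, n_stage = clin$n_stage,
                        m_stage = clin$m_stage)
forest <- do.call(rbind, lapply(colnames(dm), function(col) {
  x <- dm[clin$patient_id, col]
  keep <- !is.na(x)
  if (sum(keep) < 20) return(NULL)
  high <- as.numeric(x[keep] > median(x[keep]))
  if (length(unique(high)) < 2) return(NULL)
  uni <- cox_fit(clin$os_months[keep], clin$os_event[keep],
                 data.frame(high = high))
  adj <- cox_fit(clin$os_months[keep], clin$os_event[keep],
                 data.frame(high = high), adjusters = adjusters[keep, ])
  data.frame(density = col, n = sum(keep),
             hr = uni$hr, ci_lo = uni$ci_lo, ci_hi = uni$ci_hi, p = uni$p,
             hr_adj = adj$hr, ci_lo_adj = adj$ci_lo, ci_hi_adj = adj$ci_hi,
             p_adj = adj$p)
}))
sig <- forest[forest$p < 0.05, ]
message(sprintf("%d of %d density covariates prognostic at p<0.05 (univariate):",
                nrow(sig), nrow(forest)))
message(paste(sprintf("  %s HR=%.2f [%.2f-%.2f] p=%.3g", sig$density, sig$hr,
                      sig$ci_lo, sig$ci_hi, sig$p), collapse = "\n"))

## distance-stratified prognosis of T-lineage cells -------------------------
ec <- effective_count_matrix(cores)
strat <- distance_stratified_prognosis(
  ec[ec$phenotype %in% c("CD8T", "Treg", "Tex"), ], clin,
  strata = c("within_20", "within_30", "beyond_30"))
message("distance-stratified hazard ratios (high vs low effective count):")
ok <- strat[!strat$skipped, ]
message(paste(sprintf("  %s %s HR=%.2f p=%.3g", ok$phenotype, ok$stratum,
                      ok$hr, ok$p_cox), collapse = "\n"))

write_results(list(clinical_tests = clin_tests, forest = forest,
                   strata_hr = strat), "results/survival")
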