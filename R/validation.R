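# Validation studies: each function runs one recovery experiment end to end
# through the pipeline and returns the measured quantities. They back both
# the acceptance test suite and scripts/acceptance.R.

#' Recompute the reference clinical-table statistics from printed counts
#'
#' Runs [contingency_test()] on the printed two-array baseline
#' characteristics counts (age, gender, maximum diameter, N, M, AJCC stage,
#' OS event), the array row of the immune-subtype characteristics table, and
#' [mean_count_per_sample()] on the cohort B-cell total.
#'
#' @return data frame: `quantity`, `value` (p-value or mean), `n` (table
#'   total or sample count).
#' @export
validate_printed_tables <- function() {
  tabs <- list(
    table1_age_p = rbind(c(41, 38), c(49, 61)),
    table1_gender_p = rbind(c(42, 41), c(48, 58)),
    table1_diameter_p = rbind(c(45, 36), c(45, 63)),
    table1_n_stage_p = rbind(c(54, 52), c(24, 36), c(12, 12)),
    table1_m_stage_p = rbind(c(89, 95), c(1, 5)),
    table1_ajcc_p = rbind(c(12, 4), c(41, 47), c(36, 44), c(1, 5)),
    table1_os_event_p = rbind(c(49, 48), c(41, 52)),
    table3_array_p = rbind(c(19, 23, 13), c(36, 13, 12)))
  out <- do.call(rbind, lapply(names(tabs), function(nm)
    data.frame(quantity = nm, value = contingency_test(tabs[[nm]])$p,
               n = sum(tabs[[nm]]), stringsAsFactors = FALSE)))
  rbind(out, data.frame(quantity = "b_cell_mean_per_sample",
                        value = mean_count_per_sample(8768, 160), n = 160))
}

#' Spatial oracle equivalence study
#'
#' Generates random cores and compares the blockwise nearest-distance
#' implementation and [count_within()] against an independent brute-force
#' per-cell loop.
#'
#' @param n_cores number of random cores.
#' @param seed RNG seed.
#' @return list: `max_abs_dev` (nearest distances), `count_mismatches`
#'   (count_within vs thresholded nearest distances), `n_cells` compared.
#' @export
validate_spatial_oracle <- function(n_cores = 100, seed = 1L) {
  set.seed(seed)
  max_dev <- 0
  mismatches <- 0L
  n_cells <- 0L
  for (i in seq_len(n_cores)) {
    n_i <- sample(20:80, 1L)
    n_t <- sample(30:120, 1L)
    comp <- c(sample(c("EPI", "TME"), n_i, TRUE, prob = c(0.15, 0.85)),
              rep("EPI", n_t))
    phen <- c(sample(c("CD8T", "B", "Treg"), n_i, TRUE), rep("UNASSIGNED", n_t))
    cells <- cell_table(sprintf("c%03d", seq_len(n_i + n_t)),
                        stats::runif(n_i + n_t, 0, 600),
                        stats::runif(n_i + n_t, 0, 600),
                        comp, phenotype = phen)
    core <- core_profile("rc", "p", "T", cells, 0.1, 0.2)
    dt <- nearest_tumor_distance(core)
    # brute force: per immune cell, loop over the tumour set excluding self
    t_idx <- which(tumor_cell_set(core))
    for (j in seq_len(nrow(dt))) {
      ci <- which(cells$cell_id == dt$cell_id[j])
      others <- t_idx[t_idx != ci]
      ref <- min(sqrt((cells$x_um[others] - cells$x_um[ci])^2 +
                        (cells$y_um[others] - cells$y_um[ci])^2))
      max_dev <- max(max_dev, abs(ref - dt$distance_um[j]))
    }
    for (r in c(10, 20, 30)) for (ph in unique(dt$phenotype))
      mismatches <- mismatches +
        (count_within(core, ph, r) != sum(dt$distance_um[dt$phenotype == ph] <= r))
    n_cells <- n_cells + nrow(dt)
  }
  list(max_abs_dev = max_dev, count_mismatches = mismatches, n_cells = n_cells)
}

#' Radius-bin conservation study
#'
#' Checks on a simulated cohort that the four radius-bin counts of every
#' core and phenotype sum exactly to the phenotype's cell total.
#'
#' @param seed RNG seed.
#' @param n_patients cohort size.
#' @return list: `violations`, `n_checks`.
#' @export
validate_bin_conservation <- function(seed = 1L, n_patients = 25) {
  coh <- simulate_cohort(sim_config(n_patients = n_patients,
                                    qc_fail_rate = c(M = 0, T = 0, O = 0)),
                         seed = seed)
  cores <- apply_gating(coh$cores)
  violations <- 0L
  n_checks <- 0L
  lab <- c("(0,10]", "(10,20]", "(20,30]", "(30,Inf]")
  for (co in cores) {
    bins <- bin_effective_cells(nearest_tumor_distance(co))
    if (!nrow(bins)) next
    n_checks <- n_checks + nrow(bins)
    violations <- violations + sum(rowSums(bins[lab]) != bins$total)
  }
  list(violations = violations, n_checks = n_checks)
}

#' Proximity-kernel rank-recovery study
#'
#' Simulates cohorts with seven phenotypes at planted exponential proximity
#' kernel scales and measures the Spearman rank correlation between the
#' planted scales and the recovered cohort median nearest-tumour distances.
#'
#' @param seeds seeds, one cohort per seed.
#' @param n_patients patients per cohort.
#' @return numeric vector of per-seed rank correlations.
#' @export
validate_proximity_recovery <- function(seeds = 1:10, n_patients = 50) {
  cfg <- scenario_proximity(n_patients)
  planted <- stats::setNames(cfg$phenotypes$kernel_um, cfg$phenotypes$phenotype)
  vapply(seeds, function(s) {
    coh <- simulate_cohort(cfg, seed = s)
    md <- median_distance_summary(apply_gating(coh$cores))$cohort
    rec <- stats::setNames(md$median_of_medians_um, md$phenotype)[names(planted)]
    stats::cor(planted, rec, method = "spearman")
  }, numeric(1L))
}

#' Gating-fidelity study
#'
#' Noiseless marker emission must let the gates recover every planted
#' phenotype; the study also re-checks assignment order-invariance on the
#' same cohort.
#'
#' @param seed RNG seed.
#' @param n_patients cohort size.
#' @return list: `recovery` (fraction of planted immune labels recovered),
#'   `background_rejected` (fraction of tumour/background cells left
#'   unassigned), `order_invariant` (logical), `n_cells`.
#' @export
validate_gating_fidelity <- function(seed = 1L, n_patients = 10) {
  coh <- simulate_cohort(sim_config(n_patients = n_patients, score_noise = 0,
                                    qc_fail_rate = c(M = 0, T = 0, O = 0)),
                         seed = seed)
  panels <- default_panels()
  cores <- apply_gating(coh$cores, panels)
  assigned <- do.call(rbind, lapply(cores, function(co)
    data.frame(cell_id = co$cells$cell_id, got = co$cells$phenotype,
               stringsAsFactors = FALSE)))
  m <- merge(coh$truth$cells, assigned, by = "cell_id")
  excl <- !m$true_phenotype %in% c("Tumor", "Other")
  invariant <- TRUE
  for (co in cores[seq_len(min(6L, length(cores)))]) {
    out <- assign_phenotypes(co, panels[[co$panel_id]])
    perm <- sample(nrow(co$cells))
    co2 <- co; co2$cells <- co$cells[perm, ]
    out2 <- assign_phenotypes(co2, panels[[co$panel_id]])
    invariant <- invariant &&
      identical(out2$phenotype[match(out$cell_id, out2$cell_id)], out$phenotype)
  }
  list(recovery = mean(m$got[excl] == m$true_phenotype[excl]),
       background_rejected = mean(m$got[!excl] == "UNASSIGNED"),
       order_invariant = invariant, n_cells = nrow(m))
}

#' Planted-subtype clustering-recovery study
#'
#' Simulates cohorts with three planted infiltration groups, builds the
#' density matrix through gating, clusters patients and scores the chosen
#' cluster number and adjusted Rand index against the planted partition.
#'
#' @param seeds seeds, one cohort per seed.
#' @param n_patients patients per cohort.
#' @return data frame: `seed`, `k`, `ari`.
#' @export
validate_clustering_recovery <- function(seeds = 1:10, n_patients = 120) {
  cfg <- scenario_subtypes(n_patients)
  do.call(rbind, lapply(seeds, function(s) {
    coh <- simulate_cohort(cfg, seed = s)
    dm <- build_density_matrix(coh$cores)
    sa <- cluster_patients(dm, k_range = 2:6)
    data.frame(seed = s, k = sa$k,
               ari = adjusted_rand_index(sa$labels[names(coh$truth$subtype)],
                                         coh$truth$subtype))
  }))
}

#' Survival-recovery study
#'
#' Effect cohorts (planted per-SD log hazard ratio on the TME CD8 T-cell
#' density, ~20% censoring) measure Wald 95% CI coverage of the planted
#' effect, estimated from the gated pipeline densities; zero-log-HR cohorts
#' measure the rejection rate of a truly null density covariate.
#'
#' @param n_rep coverage-arm replicates (enough that the Monte Carlo
#'   standard error of the coverage estimate is small relative to its
#'   acceptance band).
#' @param n_rep_null null-arm replicates.
#' @param seed base seed.
#' @param log_hr planted log hazard ratio.
#' @param n_effect,n_null cohort sizes.
#' @return list: `coverage`, `null_rejection`, `mean_censoring`, `n_rep`,
#'   `n_rep_null`.
#' @export
validate_survival_recovery <- function(n_rep = 400, n_rep_null = 200,
                                       seed = 1L, log_hr = -0.7,
                                       n_effect = 200, n_null = 100) {
  seed <- as.integer(seed) %% 50000L  # keep derived seeds within integer range
  cover <- logical(n_rep)
  cens <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    coh <- simulate_cohort(scenario_survival_effect(n_effect, log_hr),
                           seed = seed * 1000L + r)
    dm <- build_density_matrix(coh$cores)
    z <- as.numeric(scale(dm[coh$clinical$patient_id, "TME.CD8T"]))
    cx <- cox_fit(coh$clinical$os_months, coh$clinical$os_event,
                  data.frame(density = z))
    cover[r] <- log(cx$ci_lo) <= log_hr && log_hr <= log(cx$ci_hi)
    cens[r] <- mean(coh$clinical$os_event == 0)
  }
  rej <- logical(n_rep_null)
  for (r in seq_len(n_rep_null)) {
    coh <- simulate_cohort(scenario_survival_null(n_null),
                           seed = seed * 2000L + r)
    dm <- build_density_matrix(coh$cores)
    z <- as.numeric(scale(dm[coh$clinical$patient_id, "TME.CD8T"]))
    cx <- cox_fit(coh$clinical$os_months, coh$clinical$os_event,
                  data.frame(density = z))
    rej[r] <- cx$p < 0.05
  }
  list(coverage = mean(cover), null_rejection = mean(rej),
       mean_censoring = mean(cens), n_rep = n_rep, n_rep_null = n_rep_null)
}

#' Distance-stratified mechanism-recovery study
#'
#' Cohorts where only CD8 T cells with a tumour cell within 20 um carry a
#' protective effect; a replicate succeeds when the 0-20 um stratum shows a
#' significant hazard ratio below 1 while the >30 um stratum stays
#' non-significant.
#'
#' @param n_rep replicates.
#' @param seed base seed.
#' @param n_patients patients per cohort.
#' @return list: `success_rate`, `within20_hits`, `beyond30_nulls`, `n_rep`.
#' @export
validate_distance_mechanism <- function(n_rep = 100, seed = 1L,
                                        n_patients = 150) {
  seed <- as.integer(seed) %% 50000L
  w20 <- logical(n_rep)
  b30 <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    coh <- simulate_cohort(scenario_distance_mechanism(n_patients),
                           seed = seed * 3000L + r)
    cores <- apply_gating(coh$cores)
    ec <- effective_count_matrix(cores, radii = c(10, 20, 30))
    res <- distance_stratified_prognosis(
      ec[ec$phenotype == "CD8T", ], coh$clinical,
      strata = c("within_20", "beyond_30"))
    a <- res[res$stratum == "within_20", ]
    b <- res[res$stratum == "beyond_30", ]
    w20[r] <- !a$skipped && a$p_cox < 0.05 && a$hr < 1
    b30[r] <- !b$skipped && b$p_cox >= 0.05
  }
  list(success_rate = mean(w20 & b30), within20_hits = mean(w20),
       beyond30_nulls = mean(b30), n_rep = n_rep)
}
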