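# Named simulation scenarios used by the validation studies. Each fixes the
# generator at the conditions of one recovery experiment; QC attrition is
# switched off so the planted sample size is the analysed sample size.

no_qc <- c(M = 0, T = 0, O = 0)

#' Validation scenarios for the synthetic cohort generator
#'
#' * `scenario_survival_effect()`: T-panel cohort with a planted log hazard
#'   ratio (default -0.7 per SD of the realised TME CD8 T-cell density),
#'   noiseless marker emission (so the gated density equals the planted
#'   covariate and the experiment isolates the Cox estimator), and ~20%
#'   administrative censoring.
#' * `scenario_survival_null()`: the same with a zero log-HR vector.
#' * `scenario_subtypes()`: three planted infiltration groups with abundance
#'   multipliers separated by well over 2 SD of the within-group density
#'   variation, for cluster-number and partition recovery.
#' * `scenario_proximity()`: seven phenotypes with widely spaced proximity
#'   kernel scales and a common small epithelial preference, for rank
#'   recovery of the planted scales from cohort median distances.
#' * `scenario_distance_mechanism()`: CD8 T cells planted as two independent
#'   subpopulations (proximal kernel 6 um, distal kernel 60 um); the hazard
#'   depends only on the realised count of CD8T cells with a tumour cell
#'   within 20 um, so the <=20 um stratum carries the protective effect and
#'   the >30 um stratum is genuinely null.
#'
#' @param n_patients cohort size of the scenario.
#' @param log_hr planted per-SD log hazard ratio.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_survival_effect <- function(n_patients = 200, log_hr = -0.7) {
  sim_config(n_patients = n_patients, panels = "T", score_noise = 0,
             qc_fail_rate = no_qc, subtypes = NULL,
             outcome = list(covariate_type = "density",
                            log_hr = c("TME.CD8T" = log_hr),
                            baseline_hazard = 0.012,
                            censor_max_months = 400))
}

#' @rdname scenarios
#' @export
scenario_survival_null <- function(n_patients = 200) {
  scenario_survival_effect(n_patients, log_hr = 0)
}

#' @rdname scenarios
#' @export
scenario_subtypes <- function(n_patients = 120) {
  # a controlled partition-recovery experiment: tissue geometry is held
  # constant across patients (otherwise shared compartment-area variation
  # elongates clusters along the infiltration gradient), phenotype counts
  # are raised and compartment preference balanced so that *every* density
  # column separates adjacent groups by at least 2 SD of its within-group
  # variation, and group multipliers are equally spaced on the density scale
  ph <- default_phenotype_table()
  ph <- ph[ph$phenotype != "CyclingCancer", ]
  ph$expected_count <- ph$expected_count * 4
  ph$pi_epi <- 0.35
  sim_config(n_patients = n_patients, score_noise = 0,
             n_nest_range = c(3L, 3L), nest_radius_range_um = c(130, 130),
             phenotypes = ph,
             qc_fail_rate = no_qc,
             subtypes = list(prob = c(0.47, 0.31, 0.22),
                             multipliers = c(1, 0.3, 1.7)),
             outcome = list(covariate_type = "density",
                            log_hr = c("TME.CD8T" = 0),
                            baseline_hazard = 0.012,
                            censor_max_months = 400))
}

#' @rdname scenarios
#' @export
scenario_proximity <- function(n_patients = 50) {
  ph <- read.table(header = TRUE, stringsAsFactors = FALSE,
             colClasses = c(panel = "character"), text = "
phenotype   panel expected_count pi_epi kernel_um
TAM2        M     30             0.05   4
Neutrophil  O     30             0.05   8
CD68        M     30             0.05   13
CD8T        T     30             0.05   20
MEC         O     30             0.05   30
B           O     30             0.05   42
Fibroblast  O     30             0.05   58
")
  sim_config(n_patients = n_patients, score_noise = 0,
             qc_fail_rate = no_qc, subtypes = NULL, phenotypes = ph,
             outcome = list(covariate_type = "density",
                            log_hr = c("TME.CD8T" = 0),
                            baseline_hazard = 0.012,
                            censor_max_months = 400))
}

#' @rdname scenarios
#' @export
scenario_distance_mechanism <- function(n_patients = 150, log_hr = -0.9) {
  ph <- read.table(header = TRUE, stringsAsFactors = FALSE,
             colClasses = c(panel = "character"), text = "
phenotype   panel expected_count pi_epi kernel_um
CD8T        T     25             0.10   6
CD8T        T     25             0.00   100
CD4Tcon     T     30             0.08   24
Treg        T     15             0.08   26
")
  # low geometry variability keeps the distal subpopulation's beyond-30 um
  # count decoupled from the proximal within-20 um count that drives the
  # hazard, so the >30 um stratum is a true null
  sim_config(n_patients = n_patients, panels = "T", score_noise = 0,
             n_nest_range = c(3L, 3L), nest_radius_range_um = c(115, 145),
             qc_fail_rate = no_qc, subtypes = NULL, phenotypes = ph,
             outcome = list(covariate_type = "effective_within",
                            phenotype = "CD8T", radius_um = 20,
                            log_hr = c("CD8T_within_20" = log_hr),
                            baseline_hazard = 0.012,
                            censor_max_months = 400))
}
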