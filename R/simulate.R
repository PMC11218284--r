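# True positive-marker map used by the score-emission model: which panel
# markers a planted phenotype genuinely expresses. "Tumor" and "Other"
# (background) cells express none.
TRUTH_MARKERS <- list(
  TAM1 = c("CD68", "CD163"), TAM2 = c("CD68", "IDO1"),
  TAM3 = c("CD68", "S100A8"), CD68 = "CD68",
  Treg = c("CD3", "FOXP3"), CD8T = c("CD3", "CD8A"), Tex = c("CD3", "TIM3"),
  CD4Tcon = "CD3",
  B = "CD20", Fibroblast = "FAP", MEC = "CD34", Neutrophil = "MPO",
  CyclingCancer = "KI67", Tumor = character(), Other = character())

PANEL_MARKERS <- list(M = c("CD68", "CD163", "IDO1", "S100A8"),
                      T = c("CD3", "CD8A", "FOXP3", "TIM3"),
                      O = c("CD20", "FAP", "CD34", "MPO", "KI67"))

default_phenotype_table <- function() {
  # per-core expected counts, compartment preference and proximity-kernel
  # scale (um); chosen to emulate the study's qualitative structure: myeloid
  # lineages nearest to tumour cells and densest in/near the epithelium,
  # T/B/stromal lineages TME-enriched and farther out, B cells averaging
  # ~55 cells per sample, TAM2 the rarest and nearest subtype
  read.table(header = TRUE, stringsAsFactors = FALSE,
             colClasses = c(panel = "character"), text = "
phenotype     panel expected_count pi_epi kernel_um
TAM1          M     40             0.35   8
TAM2          M     12             0.45   5
TAM3          M     25             0.20   12
CD68          M     35             0.40   7
CD8T          T     35             0.15   14
CD4Tcon       T     45             0.08   24
Treg          T     20             0.08   26
Tex           T     12             0.08   26
B             O     55             0.05   22
Fibroblast    O     60             0.10   30
MEC           O     40             0.10   18
Neutrophil    O     30             0.50   6
CyclingCancer O     40             1.00   NA
")
}

#' Synthetic-cohort simulation configuration
#'
#' Bundles every parameter of the generator. The defaults describe the study
#' conditions the pipeline targets: 190 patients on two TMA arrays, one
#' ~600 um-radius core per staining panel sharing the patient's tissue
#' geometry, 2-4 non-overlapping disc-shaped tumour nests per core
#' (EPI = the nests, TME = the remainder), homogeneous tumour cells inside
#' nests, phenotype-specific abundance / compartment preference / exponential
#' proximity kernels, 0-3 marker scores emitted from the phenotype's true
#' marker set with a small flip rate, per-panel QC pass rates matching the
#' study's attrition, three planted infiltration subtypes, and exponential
#' proportional-hazards survival on chosen density covariates with
#' administrative uniform censoring.
#'
#' @param n_patients cohort size.
#' @param panels staining panels to simulate (subset of `"M"`, `"T"`, `"O"`).
#' @param core_radius_um radius of the circular tissue core.
#' @param n_nest_range inclusive range for the number of tumour nests.
#' @param nest_radius_range_um range of nest disc radii.
#' @param tumor_intensity_mm2 tumour-cell intensity inside nests (cells/mm^2).
#' @param background_tme_count expected marker-negative background cells per
#'   core (kept so gating has UNASSIGNED cells to reject).
#' @param phenotypes phenotype table (`phenotype`, `panel`, `expected_count`,
#'   `pi_epi`, `kernel_um`); rows may repeat a phenotype to build mixtures.
#' @param score_noise probability that a truly positive marker reads 0 and
#'   that a truly negative marker reads a weak 1 (0 = noiseless emission).
#' @param positive_score_probs distribution of scores 1:3 for true positives.
#' @param qc_fail_rate named per-panel probability that a core fails QC.
#' @param subtypes `NULL`, or `list(prob, multipliers)` planting infiltration
#'   subtypes: each patient draws a group, and immune expected counts are
#'   scaled by the group's multiplier — either one multiplier per group, or
#'   a groups-by-phenotypes matrix (named columns) for lineage-specific
#'   infiltration profiles.
#' @param outcome survival model: `covariate_type` (`"density"` of a
#'   `"COMP.PHEN"` column, or `"effective_within"` a radius of a phenotype),
#'   `log_hr` (named vector, per standard deviation of the realised
#'   covariate), `phenotype`/`radius_um` for the effective-within type,
#'   `baseline_hazard` (events per month), `censor_max_months`
#'   (administrative uniform censoring on `[0, max]`; the default gives
#'   ~20% censoring at the default baseline hazard).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 190,
                       panels = c("M", "T", "O"),
                       core_radius_um = 600,
                       n_nest_range = c(2L, 4L),
                       nest_radius_range_um = c(90, 170),
                       tumor_intensity_mm2 = 2500,
                       background_tme_count = 80,
                       phenotypes = default_phenotype_table(),
                       score_noise = 0.02,
                       positive_score_probs = c(0.15, 0.35, 0.5),
                       qc_fail_rate = c(M = 49 / 190, T = 26 / 190, O = 30 / 190),
                       subtypes = list(prob = c(0.47, 0.31, 0.22),
                                       multipliers = c(1, 0.45, 2.2)),
                       outcome = list(covariate_type = "density",
                                      log_hr = c("TME.CD8T" = -0.7),
                                      baseline_hazard = 0.012,
                                      censor_max_months = 400)) {
  stopifnot(n_patients >= 1, core_radius_um > 0,
            all(panels %in% c("M", "T", "O")),
            all(phenotypes$expected_count >= 0),
            all(phenotypes$pi_epi >= 0 & phenotypes$pi_epi <= 1),
            abs(sum(positive_score_probs) - 1) < 1e-9,
            score_noise >= 0, score_noise < 1)
  bad_kernel <- !is.na(phenotypes$kernel_um) & phenotypes$kernel_um <= 0
  if (any(bad_kernel)) stop("proximity kernel scales must be > 0")
  if (!is.null(subtypes)) {
    k <- if (is.matrix(subtypes$multipliers)) nrow(subtypes$multipliers) else
      length(subtypes$multipliers)
    stopifnot(length(subtypes$prob) == k,
              abs(sum(subtypes$prob) - 1) < 1e-9)
    if (is.matrix(subtypes$multipliers))
      stopifnot(!is.null(colnames(subtypes$multipliers)))
  }
  structure(list(n_patients = n_patients, panels = panels,
                 core_radius_um = core_radius_um,
                 n_nest_range = as.integer(n_nest_range),
                 nest_radius_range_um = nest_radius_range_um,
                 tumor_intensity_mm2 = tumor_intensity_mm2,
                 background_tme_count = background_tme_count,
                 phenotypes = phenotypes, score_noise = score_noise,
                 positive_score_probs = positive_score_probs,
                 qc_fail_rate = qc_fail_rate, subtypes = subtypes,
                 outcome = outcome),
            class = "sim_config")
}

# Non-overlapping disc nests fully inside the circular core, so compartment
# areas are exact: EPI = sum(pi r^2), TME = core complement.
simulate_geometry <- function(config) {
  R <- config$core_radius_um
  nn_opts <- config$n_nest_range[1L]:config$n_nest_range[2L]
  n <- if (length(nn_opts) == 1L) nn_opts else sample(nn_opts, 1L)
  cx <- cy <- r <- numeric(0)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      ri <- stats::runif(1L, config$nest_radius_range_um[1L],
                         config$nest_radius_range_um[2L])
      rho <- sqrt(stats::runif(1L)) * (R - ri)
      th <- stats::runif(1L, 0, 2 * pi)
      xi <- rho * cos(th); yi <- rho * sin(th)
      if (all(sqrt((cx - xi)^2 + (cy - yi)^2) >= r + ri + 10)) {
        cx <- c(cx, xi); cy <- c(cy, yi); r <- c(r, ri)
        break
      }
    }
  }
  list(R = R, cx = cx, cy = cy, r = r,
       area_epi_mm2 = sum(pi * r^2) / 1e6,
       area_tme_mm2 = (pi * R^2 - sum(pi * r^2)) / 1e6)
}

# Uniform points inside the union of nests (nest chosen by area).
sample_in_nests <- function(geom, n) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  j <- sample.int(length(geom$r), n, replace = TRUE, prob = geom$r^2)
  rad <- geom$r[j] * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = geom$cx[j] + rad * cos(th), y = geom$cy[j] + rad * sin(th))
}

in_any_nest <- function(geom, x, y) {
  inside <- rep(FALSE, length(x))
  for (j in seq_along(geom$r))
    inside <- inside | (x - geom$cx[j])^2 + (y - geom$cy[j])^2 <= geom$r[j]^2
  inside
}

# Uniform points in the TME (core minus nests) by rejection.
sample_in_tme <- function(geom, n) {
  out <- matrix(numeric(0), 0L, 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    rho <- sqrt(stats::runif(m)) * geom$R
    th <- stats::runif(m, 0, 2 * pi)
    x <- rho * cos(th); y <- rho * sin(th)
    ok <- !in_any_nest(geom, x, y)
    out <- rbind(out, cbind(x[ok], y[ok]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

# TME points at an exponential distance from the nest boundary: draw the
# boundary offset d ~ Exp(scale), a nest (by boundary length) and an angle,
# place at nest radius + d; resample points that leave the core or land in
# another nest.
sample_near_boundary <- function(geom, n, scale) {
  x <- y <- rep(NA_real_, n)
  todo <- seq_len(n)
  for (iter in 1:60) {
    m <- length(todo)
    if (!m) break
    d <- stats::rexp(m, rate = 1 / scale)
    j <- sample.int(length(geom$r), m, replace = TRUE, prob = geom$r)
    th <- stats::runif(m, 0, 2 * pi)
    xi <- geom$cx[j] + (geom$r[j] + d) * cos(th)
    yi <- geom$cy[j] + (geom$r[j] + d) * sin(th)
    ok <- xi^2 + yi^2 <= geom$R^2 & !in_any_nest(geom, xi, yi)
    x[todo[ok]] <- xi[ok]; y[todo[ok]] <- yi[ok]
    todo <- todo[!ok]
  }
  if (length(todo)) {  # pathological kernel/geometry: fall back to uniform TME
    fb <- sample_in_tme(geom, length(todo))
    x[todo] <- fb[, 1L]; y[todo] <- fb[, 2L]
  }
  cbind(x = x, y = y)
}

# Emit 0-3 scores for one panel's markers given true phenotypes.
emit_scores <- function(true_phen, markers, config) {
  n <- length(true_phen)
  out <- as.data.frame(matrix(0L, n, length(markers),
                              dimnames = list(NULL, markers)))
  pos_probs <- config$positive_score_probs
  uph <- unique(true_phen)
  for (m in markers) {
    pos_phens <- uph[vapply(uph, function(p) m %in% TRUTH_MARKERS[[p]],
                            logical(1L))]
    truly_pos <- true_phen %in% pos_phens
    s <- integer(n)
    npos <- sum(truly_pos)
    if (npos) s[truly_pos] <- sample(1:3, npos, replace = TRUE, prob = pos_probs)
    if (config$score_noise > 0) {
      drop <- truly_pos & stats::runif(n) < config$score_noise
      gain <- !truly_pos & stats::runif(n) < config$score_noise
      s[drop] <- 0L
      s[gain] <- 1L
    }
    out[[m]] <- s
  }
  out
}

#' Simulate one tissue core
#'
#' Samples tumour cells as a homogeneous point process inside the patient's
#' tumour nests, places each panel phenotype in a compartment by its
#' `pi_epi` preference (EPI cells uniform within nests; TME cells at an
#' exponential distance from the nest boundary with the phenotype's kernel
#' scale), emits marker scores from the phenotype's true marker set, and
#' records ground truth for every cell. Compartment areas are exact from the
#' disc geometry.
#'
#' @param config a [sim_config()].
#' @param patient_state list with `patient_id`, `geometry`
#'   (from the patient's shared tissue geometry), `multiplier` (subtype
#'   abundance multiplier).
#' @param panel_id which panel's core to simulate.
#' @return list: `core` (a [core_profile()]), `truth` (data frame
#'   `cell_id`, `true_phenotype`).
#' @export
simulate_core <- function(config, patient_state, panel_id) {
  geom <- patient_state$geometry
  panel_markers <- PANEL_MARKERS[[panel_id]]
  ph <- config$phenotypes[config$phenotypes$panel == panel_id, , drop = FALSE]
  n_tumor <- stats::rpois(1L, config$tumor_intensity_mm2 * geom$area_epi_mm2)
  xy <- sample_in_nests(geom, n_tumor)
  phen <- rep("Tumor", n_tumor)
  comp <- rep("EPI", n_tumor)
  for (i in seq_len(nrow(ph))) {
    mult <- patient_state$multiplier
    if (length(mult) > 1L)
      mult <- if (ph$phenotype[i] %in% names(mult)) mult[[ph$phenotype[i]]] else 1
    lambda <- ph$expected_count[i] *
      (if (ph$phenotype[i] %in% c("CyclingCancer")) 1 else mult)
    n_i <- stats::rpois(1L, lambda)
    if (!n_i) next
    n_epi <- stats::rbinom(1L, n_i, ph$pi_epi[i])
    pts <- rbind(sample_in_nests(geom, n_epi),
                 if (n_i - n_epi > 0)
                   sample_near_boundary(geom, n_i - n_epi, ph$kernel_um[i])
                 else NULL)
    xy <- rbind(xy, pts)
    phen <- c(phen, rep(ph$phenotype[i], n_i))
    comp <- c(comp, rep(c("EPI", "TME"), c(n_epi, n_i - n_epi)))
  }
  n_bg <- stats::rpois(1L, config$background_tme_count)
  if (n_bg) {
    xy <- rbind(xy, sample_in_tme(geom, n_bg))
    phen <- c(phen, rep("Other", n_bg))
    comp <- c(comp, rep("TME", n_bg))
  }
  core_id <- paste0(patient_state$patient_id, "_", panel_id)
  cell_id <- sprintf("%s_c%05d", core_id, seq_along(phen))
  cells <- cell_table(cell_id = cell_id, x_um = xy[, 1L], y_um = xy[, 2L],
                      compartment = comp,
                      scores = emit_scores(phen, panel_markers, config))
  qc_fail <- config$qc_fail_rate[panel_id]
  qc_pass <- if (is.na(qc_fail) || qc_fail <= 0) TRUE else
    stats::runif(1L) >= qc_fail
  core <- core_profile(core_id = core_id,
                       patient_id = patient_state$patient_id,
                       panel_id = panel_id, cells = cells,
                       area_epi_mm2 = geom$area_epi_mm2,
                       area_tme_mm2 = geom$area_tme_mm2, qc_pass = qc_pass)
  list(core = core,
       truth = data.frame(cell_id = cell_id, true_phenotype = phen,
                          stringsAsFactors = FALSE))
}

sample_clinical <- function(patient_ids) {
  n <- length(patient_ids)
  array <- sample(c("sur05", "sur10"), n, replace = TRUE, prob = c(90, 100) / 190)
  location <- ifelse(array == "sur05", "Rectum",
                     sample(c("Right colon", "Left colon"), n, replace = TRUE,
                            prob = c(50, 42) / 92))
  data.frame(patient_id = patient_ids,
             age_group = sample(c("<65", ">=65"), n, TRUE, c(79, 110) / 189),
             sex = sample(c("Female", "Male"), n, TRUE, c(83, 106) / 189),
             location = location,
             size_group = sample(c("<5", ">=5"), n, TRUE, c(81, 108) / 189),
             t_stage = sample(paste0("T", 1:4), n, TRUE, c(2, 14, 140, 33) / 189),
             n_stage = sample(paste0("N", 0:2), n, TRUE, c(106, 60, 24) / 190),
             m_stage = sample(c("M0", "M1"), n, TRUE, c(184, 6) / 190),
             ajcc = sample(paste0("AJCC", 1:4), n, TRUE, c(16, 88, 80, 6) / 190),
             array = array,
             os_months = 0, os_event = 0L, stringsAsFactors = FALSE)
}

# Realised covariate per patient for the planted outcome model, computed
# from ground truth (not from gating).
planted_covariates <- function(config, cores, truths) {
  oc <- config$outcome
  patients <- sort(unique(vapply(cores, `[[`, "", "patient_id")))
  if (identical(oc$covariate_type, "density")) {
    vals <- vapply(names(oc$log_hr), function(key) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
      comp <- parts[1L]; phen <- paste(parts[-1L], collapse = ".")
      panel_id <- config$phenotypes$panel[match(phen, config$phenotypes$phenotype)]
      v <- stats::setNames(rep(NA_real_, length(patients)), patients)
      for (i in seq_along(cores)) {
        co <- cores[[i]]
        if (co$panel_id != panel_id) next
        tr <- truths[[i]]
        cnt <- sum(tr$true_phenotype == phen & co$cells$compartment == comp)
        v[co$patient_id] <- cnt / compartment_area(co, comp)
      }
      v
    }, numeric(length(patients)))
    out <- matrix(vals, ncol = length(oc$log_hr),
                  dimnames = list(patients, names(oc$log_hr)))
  } else if (identical(oc$covariate_type, "effective_within")) {
    phen <- oc$phenotype
    panel_id <- config$phenotypes$panel[match(phen, config$phenotypes$phenotype)]
    v <- stats::setNames(rep(NA_real_, length(patients)), patients)
    for (i in seq_along(cores)) {
      co <- cores[[i]]
      if (co$panel_id != panel_id) next
      tr <- truths[[i]]
      is_ph <- tr$true_phenotype == phen
      is_tu <- tr$true_phenotype %in% c("Tumor", "CyclingCancer")
      d <- nn_min_dist(co$cells$x_um[is_ph], co$cells$y_um[is_ph],
                       co$cells$x_um[is_tu], co$cells$y_um[is_tu])
      v[co$patient_id] <- sum(d <= oc$radius_um, na.rm = TRUE)
    }
    out <- matrix(v, ncol = 1L,
                  dimnames = list(patients, names(oc$log_hr)[1L]))
  } else stop("unknown covariate_type: ", oc$covariate_type)
  out
}

#' Simulate a complete synthetic cohort
#'
#' Draws per-patient tissue geometry (shared across the patient's panels, so
#' tumour purity is consistent between panels), simulates one core per
#' staining panel, samples clinical covariates from study-like marginals,
#' and generates overall survival from an exponential proportional-hazards
#' model on the z-scored realised outcome covariates with administrative
#' uniform censoring. Everything is determined by `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list of class `synthetic_cohort`: `cores` (named list of
#'   [core_profile()]), `clinical` (validated clinical table), `truth`
#'   (list: `cells` per-cell true phenotypes, `subtype` per-patient planted
#'   group, `covariates` realised outcome covariates, `z` their z-scores,
#'   `log_hr`), `config`, `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(config$n_patients))
  subtype <- if (is.null(config$subtypes)) rep(1L, config$n_patients) else
    sample(seq_along(config$subtypes$prob), config$n_patients, replace = TRUE,
           prob = config$subtypes$prob)
  mult <- if (is.null(config$subtypes)) {
    rep(1, config$n_patients)
  } else if (is.matrix(config$subtypes$multipliers)) {
    lapply(subtype, function(g) config$subtypes$multipliers[g, ])
  } else config$subtypes$multipliers[subtype]
  clinical <- sample_clinical(ids)
  cores <- list()
  truths <- list()
  for (i in seq_along(ids)) {
    state <- list(patient_id = ids[i], geometry = simulate_geometry(config),
                  multiplier = if (is.list(mult)) mult[[i]] else mult[i])
    for (panel_id in config$panels) {
      sim <- simulate_core(config, state, panel_id)
      cores[[sim$core$core_id]] <- sim$core
      truths[[sim$core$core_id]] <- sim$truth
    }
  }
  oc <- config$outcome
  covars <- planted_covariates(config, cores, truths)
  z <- apply(covars, 2L, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  beta <- unname(oc$log_hr[colnames(covars)])
  beta[is.na(beta)] <- 0
  lp <- as.numeric(z %*% beta)
  rate <- oc$baseline_hazard * exp(lp)
  t_event <- stats::rexp(length(ids), rate = rate)
  c_admin <- stats::runif(length(ids), 0, oc$censor_max_months)
  clinical$os_months <- round(pmin(t_event, c_admin), 2)
  clinical$os_event <- as.integer(t_event <= c_admin)
  truth_cells <- do.call(rbind, Map(function(core_id, tr)
    cbind(core_id = core_id, tr, stringsAsFactors = FALSE),
    names(truths), truths))
  rownames(truth_cells) <- NULL
  structure(list(cores = cores,
                 clinical = validate_clinical_table(clinical),
                 truth = list(cells = truth_cells,
                              subtype = stats::setNames(paste0("G", subtype), ids),
                              covariates = covars, z = z,
                              log_hr = oc$log_hr),
                 config = config, seed = seed),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort in the pipeline's input dialects
#'
#' Emits the same file formats [read_cell_table()], [read_segment_summary()]
#' and [read_clinical_table()] consume, plus ground-truth tables, so the
#' generator can feed the pipeline end to end through its I/O layer.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param out_dir output directory.
#' @param dialect an [inform_dialect()].
#' @return invisible vector of file paths written.
#' @export
write_cohort <- function(cohort, out_dir, dialect = inform_dialect()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cells = file.path(out_dir, "cell_seg_data.txt"),
             summary = file.path(out_dir, "cell_seg_data_summary.txt"),
             clinical = file.path(out_dir, "clinical.tsv"),
             truth = file.path(out_dir, "truth_cells.tsv"))
  write_cell_table(cohort$cores, paths["cells"], dialect)
  write_segment_summary(cohort$cores, paths["summary"], dialect)
  write_clinical_table(cohort$clinical, paths["clinical"])
  utils::write.table(cohort$truth$cells, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a cohort back from its on-disk form
#' @param dir directory written by [write_cohort()].
#' @param dialect an [inform_dialect()].
#' @return list with `cores` and `clinical`.
#' @export
read_cohort <- function(dir, dialect = inform_dialect()) {
  cores <- read_cell_table(file.path(dir, "cell_seg_data.txt"), dialect)
  summ <- read_segment_summary(file.path(dir, "cell_seg_data_summary.txt"), dialect)
  cores <- attach_segment_summary(cores, summ)
  list(cores = cores,
       clinical = read_clinical_table(file.path(dir, "clinical.tsv")))
}
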