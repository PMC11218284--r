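test_that("H-score follows the weighted-proportion formula over its full range", {
  all0 <- make_cells(1:4, 1:4, "TME", scores = list(CD3 = rep(0L, 4)))
  expect_equal(h_score(all0, "CD3")$h_score, 0)
  all3 <- make_cells(1:4, 1:4, "TME", scores = list(CD3 = rep(3L, 4)))
  expect_equal(h_score(all3, "CD3")$h_score, 300)
  # proportions (p1, p2, p3) = (0.5, 0.25, 0.25)
  mix <- make_cells(1:4, 1:4, "TME", scores = list(CD3 = c(1L, 1L, 2L, 3L)))
  expect_equal(h_score(mix, "CD3")$h_score, 175)
  expect_equal(h_score(mix, "CD3")$p1, 0.5)
  epi_only <- make_cells(1:2, 1:2, "EPI", scores = list(CD3 = c(3L, 3L)))
  expect_error(h_score(epi_only, "CD3", compartment = "TME"), "no cells")
  expect_error(h_score(mix, "CD99"), "not scored")
})

test_that("H-score is bounded, order-invariant and duplication-invariant", {
  set.seed(401)
  for (rep in 1:20) {
    n <- sample(3:40, 1L)
    s <- sample(0:3, n, replace = TRUE)
    cells <- make_cells(seq_len(n), seq_len(n), "TME", scores = list(M = s))
    h <- h_score(cells, "M")$h_score
    expect_gte(h, 0); expect_lte(h, 300)
    expect_equal(h == 300, all(s == 3L))
    perm <- cells[sample(n), ]
    expect_equal(h_score(perm, "M")$h_score, h)
    dup <- rbind(cells, cells)
    expect_equal(h_score(dup, "M")$h_score, h)
    expect_equal(sum(unlist(h_score(cells, "M")[c("p0", "p1", "p2", "p3")])), 1)
  }
})

test_that("marker positivity is score >= threshold with scores 1-3 positive by default", {
  cells <- make_cells(1:4, 1:4, "TME", scores = list(CD3 = c(0L, 1L, 2L, 3L)))
  expect_identical(is_positive(cells, "CD3"), c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(is_positive(cells, "CD3", threshold = 2L),
                   c(FALSE, FALSE, TRUE, TRUE))
  na <- make_cells(1, 1, "TME", scores = list(CD3 = NA_integer_))
  expect_error(is_positive(na, "CD3"), "unscored")
})

test_that("density divides compartment counts by the compartment's own area", {
  cells <- make_cells(seq_len(40), seq_len(40),
                      rep(c("TME", "EPI"), c(30, 10)),
                      phenotype = rep(c("B", "UNASSIGNED"), c(30, 10)))
  core <- make_core(cells, area_epi = 0.1, area_tme = 0.5)
  expect_equal(density_per_mm2(core, "B", "TME"), 60)
  expect_equal(density_per_mm2(core, "B", "EPI"), 0)
  zero_area <- make_core(cells, area_epi = 0.1, area_tme = 0)
  expect_error(density_per_mm2(zero_area, "B", "TME"), "zero TME area")
  empty_ok <- make_core(cells[cells$compartment == "EPI", ], area_tme = 0)
  expect_equal(density_per_mm2(empty_ok, "B", "TME"), 0)
  # doubling counts at fixed area doubles density
  dbl <- make_core(rbind(cells, cells), area_epi = 0.1, area_tme = 0.5)
  expect_equal(density_per_mm2(dbl, "B", "TME"),
               2 * density_per_mm2(core, "B", "TME"))
})

test_that("simulated tumour-cell density recovers the planted intensity (Poisson oracle)", {
  set.seed(402)
  cfg <- sim_config(n_patients = 1, panels = "T", tumor_intensity_mm2 = 800,
                    background_tme_count = 0, score_noise = 0,
                    phenotypes = data.frame(phenotype = character(),
                                            panel = character(),
                                            expected_count = numeric(),
                                            pi_epi = numeric(),
                                            kernel_um = numeric()),
                    qc_fail_rate = c(M = 0, T = 0, O = 0), subtypes = NULL)
  dens <- replicate(200, {
    geom <- immunocontext:::simulate_geometry(cfg)
    sim <- simulate_core(cfg, list(patient_id = "P1", geometry = geom,
                                   multiplier = 1), "T")
    nrow(sim$core$cells) / geom$area_epi_mm2
  })
  se <- stats::sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - 800), 3 * se + 1e-9)
})

test_that("tumour purity is the epithelial cell fraction", {
  cells <- make_cells(seq_len(200), seq_len(200),
                      rep(c("EPI", "TME"), c(120, 80)))
  expect_equal(tumor_purity(make_core(cells))$purity, 0.6)
  tme_only <- make_cells(1:5, 1:5, "TME")
  expect_equal(tumor_purity(make_core(tme_only))$purity, 0)
  epi_only <- make_cells(1:5, 1:5, "EPI")
  expect_equal(tumor_purity(make_core(epi_only))$purity, 1)
  expect_error(tumor_purity(make_core(make_cells(numeric(), numeric(), character()))),
               "empty core")
})

test_that("purity is consistent across panels sharing the same tissue geometry", {
  coh <- simulate_cohort(sim_config(n_patients = 40,
                                    qc_fail_rate = c(M = 0, T = 0, O = 0)),
                         seed = 403)
  pur <- sapply(c("M", "T", "O"), function(p)
    vapply(sprintf("P%04d_%s", 1:40, p),
           function(id) tumor_purity(coh$cores[[id]])$purity, numeric(1L)))
  cc <- stats::cor(pur)
  expect_true(all(cc[upper.tri(cc)] > 0.9))
})

test_that("mean count per sample reproduces the cohort B-cell average", {
  expect_equal(mean_count_per_sample(8768, 160), 54.8)
  expect_equal(mean_count_per_sample(0, 10), 0)
  for (k in c(3, 17)) expect_equal(mean_count_per_sample(k * 12, 12), k)
  expect_error(mean_count_per_sample(10, 0), "> 0")
})
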