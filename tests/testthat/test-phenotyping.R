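test_that("negative-screening gates reproduce the canonical marker combinations", {
  # T panel: subsets before the residual conventional CD4 gate
  expect_equal(gate_one(CD3 = 2L, CD8A = 3L), "CD8T")
  expect_equal(gate_one(CD3 = 2L), "CD4Tcon")
  expect_equal(gate_one(CD3 = 1L, TIM3 = 2L), "Tex")
  expect_equal(gate_one(CD3 = 1L, FOXP3 = 1L, CD8A = 2L), "Treg")
  expect_equal(gate_one(CD8A = 3L), "UNASSIGNED")  # CD3- cells are never T cells
  expect_equal(gate_one(), "UNASSIGNED")
  # CD8A+TIM3+ resolves to CD8T by default gate order; alternative reading optional
  expect_equal(gate_one(CD3 = 1L, CD8A = 1L, TIM3 = 1L), "CD8T")
  alt <- default_panels(tex_before_cd8t = TRUE)$T
  expect_equal(gate_one(CD3 = 1L, CD8A = 1L, TIM3 = 1L, panel = alt), "Tex")

  m <- default_panels()$M
  expect_equal(gate_one(CD68 = 2L, IDO1 = 1L, panel = m), "TAM2")
  expect_equal(gate_one(CD68 = 2L, CD163 = 2L, panel = m), "TAM1")
  expect_equal(gate_one(CD68 = 2L, S100A8 = 3L, panel = m), "TAM3")
  expect_equal(gate_one(CD68 = 2L, panel = m), "CD68")
  # multi-positive macrophages resolved by configurable priority
  expect_equal(gate_one(CD68 = 2L, CD163 = 1L, IDO1 = 1L, panel = m), "TAM2")
  m_alt <- default_panels(m_priority = c("TAM1", "TAM2", "TAM3"))$M
  expect_equal(gate_one(CD68 = 2L, CD163 = 1L, IDO1 = 1L, panel = m_alt), "TAM1")

  o <- default_panels()$O
  expect_equal(gate_one(CD20 = 2L, panel = o), "B")
  expect_equal(gate_one(CD20 = 2L, FAP = 1L, panel = o), "UNASSIGNED")
  expect_equal(gate_one(KI67 = 3L, compartment = "EPI", panel = o), "CyclingCancer")
  expect_equal(gate_one(KI67 = 3L, compartment = "TME", panel = o), "UNASSIGNED")
})

test_that("panel and gate configuration is validated", {
  expect_error(gate_rule("X", "CD3", "CD3"), "both positive and negative")
  expect_error(panel_config("P", markers = "CD3",
                            gates = list(gate_rule("X", "CD99"))), "absent")
  expect_error(panel_config("P", markers = c("CD3", "CD8A"),
                            gates = list(gate_rule("X", "CD3"),
                                         gate_rule("X", "CD8A"))), "duplicate")
  cells <- make_cells(1, 1, "TME", scores = list(CD3 = 1L))
  expect_error(assign_phenotypes(cells, default_panels()$T), "missing score")
})

test_that("gating is order-invariant, exclusive and monotone in negative requirements", {
  set.seed(404)
  panel <- default_panels()$T
  for (rep in 1:10) {
    n <- 80
    cells <- make_cells(runif(n), runif(n), sample(c("EPI", "TME"), n, TRUE),
                        scores = lapply(setNames(panel$markers, panel$markers),
                                        function(m) sample(0:3, n, TRUE)))
    out <- assign_phenotypes(cells, panel)
    expect_equal(nrow(out), n)           # exactly one outcome per cell
    perm <- sample(n)
    out_p <- assign_phenotypes(cells[perm, ], panel)
    expect_identical(out_p$phenotype[match(out$cell_id, out_p$cell_id)],
                     out$phenotype)
    # adding a required-negative marker can only shrink the phenotype
    stricter <- panel
    stricter$gates[[2L]] <- gate_rule("CD8T", c("CD3", "CD8A"),
                                      c("FOXP3", "TIM3"))
    out_s <- assign_phenotypes(cells, stricter)
    expect_lte(sum(out_s$phenotype == "CD8T"), sum(out$phenotype == "CD8T"))
  }
})

test_that("phenotype counts conserve totals and recover planted frequencies exactly", {
  cfg <- sim_config(n_patients = 3, score_noise = 0,
                    qc_fail_rate = c(M = 0, T = 0, O = 0), subtypes = NULL)
  coh <- simulate_cohort(cfg, seed = 405)
  panels <- default_panels()
  for (id in names(coh$cores)) {
    co <- coh$cores[[id]]
    panel <- panels[[co$panel_id]]
    pc <- phenotype_counts(co, panel)
    excl <- pc[!pc$pan, ]
    expect_equal(sum(excl$n), nrow(co$cells))  # conservation incl. UNASSIGNED
    truth <- coh$truth$cells[coh$truth$cells$core_id == id, ]
    for (ph in setdiff(unique(truth$true_phenotype), c("Tumor", "Other")))
      expect_equal(sum(excl$n[excl$phenotype == ph]),
                   sum(truth$true_phenotype == ph),
                   label = paste(id, ph))
  }
})

test_that("CD3T is a pan tally by default and a leftover tally in literal mode", {
  panel <- default_panels()$T
  cells <- make_cells(1:4, 1:4, "TME",
                      scores = list(CD3 = c(1L, 1L, 1L, 0L),
                                    CD8A = c(1L, 0L, 0L, 0L),
                                    FOXP3 = c(0L, 0L, 0L, 0L),
                                    TIM3 = c(0L, 0L, 0L, 0L)))
  pc <- phenotype_counts(make_core(cells), panel)
  expect_equal(sum(pc$n[pc$phenotype == "CD3T"]), 3L)  # every CD3+ cell
  expect_true(all(pc$pan[pc$phenotype == "CD3T"]))
  left <- default_panels(cd3t_mode = "leftover")$T
  pc2 <- phenotype_counts(make_core(cells), left)
  expect_equal(sum(pc2$n[pc2$phenotype == "CD3T"]), 0L)  # all CD3+ were gated
})

test_that("an empty core yields an all-zero count table", {
  empty <- make_cells(numeric(), numeric(), character(),
                      scores = lapply(setNames(nm = default_panels()$T$markers),
                                      function(m) integer()))
  pc <- phenotype_counts(make_core(empty), default_panels()$T)
  expect_true(all(pc$n == 0L))
})

test_that("panel configurations survive a YAML round trip", {
  panel <- default_panels()$T
  f <- withr::local_tempfile(fileext = ".yaml")
  write_panel_config(panel, f)
  back <- read_panel_config(f)
  set.seed(406)
  n <- 50
  cells <- make_cells(runif(n), runif(n), "TME",
                      scores = lapply(setNames(nm = panel$markers),
                                      function(m) sample(0:3, n, TRUE)))
  expect_identical(assign_phenotypes(cells, back)$phenotype,
                   assign_phenotypes(cells, panel)$phenotype)
  expect_identical(back$pan_phenotypes, panel$pan_phenotypes)
})
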