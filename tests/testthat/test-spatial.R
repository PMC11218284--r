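test_that("nearest tumour distance is the exact Euclidean minimum", {
  cells <- make_cells(c(0, 3, 6), c(0, 4, 8),
                      c("TME", "EPI", "EPI"),
                      phenotype = c("CD8T", "UNASSIGNED", "UNASSIGNED"))
  dt <- nearest_tumor_distance(make_core(cells))
  expect_equal(dt$distance_um, 5)
  # coincident immune and tumour cells are at distance zero
  co <- make_cells(c(10, 10), c(7, 7), c("TME", "EPI"),
                   phenotype = c("B", "UNASSIGNED"))
  expect_equal(nearest_tumor_distance(make_core(co))$distance_um, 0)
  # a core without tumour cells yields flagged missing distances, not zeros
  no_t <- make_cells(1:3, 1:3, "TME", phenotype = c("B", "B", "CD8T"))
  dt0 <- nearest_tumor_distance(make_core(no_t))
  expect_true(attr(dt0, "no_tumor"))
  expect_true(all(is.na(dt0$distance_um)))
})

test_that("an immune cell inside the epithelium measures to its nearest neighbour, not itself", {
  cells <- make_cells(c(0, 30), c(0, 0), c("EPI", "EPI"),
                      phenotype = c("CD8T", "UNASSIGNED"))
  dt <- nearest_tumor_distance(make_core(cells))
  expect_equal(dt$distance_um, 30)
  expect_equal(count_within(make_core(cells), "CD8T", 10), 0L)
  expect_equal(count_within(make_core(cells), "CD8T", 30), 1L)
})

test_that("blockwise nearest-neighbour equals the brute-force oracle to 1e-9", {
  set.seed(407)
  qx <- runif(500, 0, 1000); qy <- runif(500, 0, 1000)
  rx <- runif(300, 0, 1000); ry <- runif(300, 0, 1000)
  fast <- immunocontext:::nn_min_dist(qx, qy, rx, ry, block = 64L)
  slow <- brute_nn(qx, qy, rx, ry)
  expect_lt(max(abs(fast - slow)), 1e-9)
  # translation and rotation invariance
  th <- 0.83
  rot <- function(x, y) list(x = x * cos(th) - y * sin(th) + 55,
                             y = x * sin(th) + y * cos(th) - 12)
  q2 <- rot(qx, qy); r2 <- rot(rx, ry)
  expect_equal(immunocontext:::nn_min_dist(q2$x, q2$y, r2$x, r2$y), fast,
               tolerance = 1e-9)
})

test_that("count_within matches its definitional equivalence with nearest distances", {
  cells <- make_cells(c(0, 5, 15), c(0, 0, 0), c("TME", "EPI", "EPI"),
                      phenotype = c("B", "UNASSIGNED", "UNASSIGNED"))
  core <- make_core(cells)
  expect_equal(count_within(core, "B", 10), 1L)
  expect_equal(count_within(core, "B", 4), 0L)
  expect_error(count_within(core, "B", -1), "radius")
  set.seed(408)
  for (rep in 1:30) {
    core <- random_core(n_immune = 40, n_tumor = 50)
    dt <- nearest_tumor_distance(core)
    for (r in c(10, 20, 30)) {
      for (ph in unique(dt$phenotype)) {
        expect_identical(count_within(core, ph, r),
                         sum(dt$distance_um[dt$phenotype == ph] <= r))
      }
    }
  }
})

test_that("radius bins are half-open with inclusive printed thresholds and conserve totals", {
  d <- c(5, 10, 10.1, 25, 40)
  cells <- make_cells(c(d, 0), rep(0, 6), c(rep("TME", 5), "EPI"),
                      phenotype = c(rep("B", 5), "UNASSIGNED"))
  bins <- bin_effective_cells(nearest_tumor_distance(make_core(cells)))
  expect_equal(unlist(bins[1, c("(0,10]", "(10,20]", "(20,30]", "(30,Inf]")],
                      use.names = FALSE), c(2L, 1L, 1L, 1L))
  expect_equal(bins$total, 5L)
  near <- make_cells(c(1, 2, 3, 0), rep(0, 4), c(rep("TME", 3), "EPI"),
                     phenotype = c(rep("B", 3), "UNASSIGNED"))
  b2 <- bin_effective_cells(nearest_tumor_distance(make_core(near)))
  expect_equal(unlist(b2[1, c("(0,10]", "(10,20]", "(20,30]", "(30,Inf]")],
                      use.names = FALSE), c(3L, 0L, 0L, 0L))
  set.seed(409)
  for (rep in 1:20) {
    core <- random_core()
    bins <- bin_effective_cells(nearest_tumor_distance(core))
    lab <- c("(0,10]", "(10,20]", "(20,30]", "(30,Inf]")
    expect_equal(rowSums(bins[lab]), as.numeric(bins$total))
    expect_equal(sum(bins$total), sum(table(core$cells$phenotype)[unique(bins$phenotype)]))
  }
})

test_that("median summaries use per-core medians then the cohort distribution", {
  cells <- make_cells(c(1, 2, 3, 0), rep(0, 4), c(rep("TME", 3), "EPI"),
                      phenotype = c(rep("B", 3), "UNASSIGNED"))
  md <- median_distance_summary(list(make_core(cells)))
  expect_equal(md$cohort$median_of_medians_um, 2)
  # a phenotype absent from a core is omitted from that core's summary
  expect_false("CD8T" %in% md$per_core$phenotype)
})

test_that("planted proximity-kernel scales order the recovered median distances", {
  cfg <- sim_config(n_patients = 20, panels = "T", score_noise = 0,
                    qc_fail_rate = c(M = 0, T = 0, O = 0), subtypes = NULL,
                    phenotypes = data.frame(
                      phenotype = c("CD8T", "Treg"), panel = "T",
                      expected_count = 30, pi_epi = 0.05,
                      kernel_um = c(5, 25), stringsAsFactors = FALSE))
  coh <- simulate_cohort(cfg, seed = 410)
  md <- median_distance_summary(apply_gating(coh$cores))$cohort
  med <- setNames(md$median_of_medians_um, md$phenotype)
  expect_lt(med[["CD8T"]], med[["Treg"]])
})

test_that("patient-level effective counts are cumulative in the radius", {
  coh <- simulate_cohort(sim_config(n_patients = 4, panels = "T",
                                    qc_fail_rate = c(M = 0, T = 0, O = 0),
                                    subtypes = NULL), seed = 411)
  ec <- effective_count_matrix(apply_gating(coh$cores))
  expect_true(all(ec$within_10 <= ec$within_20))
  expect_true(all(ec$within_20 <= ec$within_30))
  expect_equal(ec$within_30 + ec$beyond_30, ec$total)
})
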