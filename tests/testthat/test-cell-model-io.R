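test_that("cell table validation enforces scores, compartments and coordinates", {
  ok <- make_cells(1:3, 4:6, c("EPI", "TME", "EPI"),
                   scores = list(CD3 = c(0L, 1L, 3L)))
  expect_s3_class(ok, "cell_table")
  expect_identical(marker_names(ok), "CD3")
  expect_error(make_cells(1, 2, "EPI", scores = list(CD3 = 4L)), "0,1,2,3")
  expect_error(make_cells(1, 2, "stroma"), "compartment")
  expect_error(make_cells(Inf, 2, "EPI"), "coordinates")
  expect_error(core_profile("c", "p", "T", ok, area_epi_mm2 = -1), ">= 0")
})

test_that("inForm-dialect tables parse with category mapping, score and unit handling", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "Sample Name\tCell ID\tCell X Position\tCell Y Position\tTissue Category\tCD3 Score\tCD8A Score",
    "core_a\t1\t10\t20\tTumor\t0\t3",
    "core_a\t2\t30\t40\tStroma\t1\t2",
    "core_a\t3\t50\t60\tStroma\t2\t0"), f)
  cores <- read_cell_table(f)
  expect_length(cores, 1L)
  cells <- cores[[1L]]$cells
  expect_identical(cells$compartment, c("EPI", "TME", "TME"))
  expect_identical(cells$CD3, c(0L, 1L, 2L))
  expect_identical(cells$CD8A, c(3L, 2L, 0L))
  expect_equal(cells$x_um, c(10, 30, 50))
  # pixel-unit dialect applies the microns-per-pixel scale at ingest
  px <- read_cell_table(f, inform_dialect(unit = "pixel", microns_per_pixel = 0.5))
  expect_equal(px[[1L]]$cells$x_um, c(5, 15, 25))
})

test_that("malformed inputs fail loudly with the offending column, row or value", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Sample Name\tCell ID\tCell X Position\tTissue Category",
               "a\t1\t1\tTumor"), f)
  expect_error(read_cell_table(f), "Cell Y Position")
  writeLines(c("Sample Name\tCell ID\tCell X Position\tCell Y Position\tTissue Category",
               "a\t1\toops\t2\tTumor"), f)
  expect_error(read_cell_table(f), "row")
  writeLines(c("Sample Name\tCell ID\tCell X Position\tCell Y Position\tTissue Category",
               "a\t1\t1\t2\tNecrosis"), f)
  expect_error(read_cell_table(f), "Necrosis")
})

test_that("clinical tables validate vocabularies, ids and survival fields", {
  coh <- simulate_cohort(sim_config(n_patients = 6, panels = "T"), seed = 11)
  clin <- coh$clinical
  expect_silent(validate_clinical_table(clin))
  dup <- rbind(clin, clin[1L, ])
  expect_error(validate_clinical_table(dup), "duplicate patient_id")
  bad <- clin; bad$os_event[2L] <- 2L
  expect_error(validate_clinical_table(bad), "os_event")
  bad <- clin; bad$t_stage[1L] <- "T9"
  expect_error(validate_clinical_table(bad), "vocabulary")
  f <- withr::local_tempfile(fileext = ".tsv")
  bad <- clin; bad$os_months <- as.character(bad$os_months); bad$os_months[3L] <- "n/a"
  utils::write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_clinical_table(f), "os_months")
})

test_that("a synthetic cohort round-trips through the on-disk dialects", {
  coh <- simulate_cohort(sim_config(n_patients = 4), seed = 21)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_setequal(names(back$cores), names(coh$cores))
  for (id in names(coh$cores)) {
    a <- coh$cores[[id]]; b <- back$cores[[id]]
    expect_identical(b$patient_id, a$patient_id)
    expect_identical(b$panel_id, a$panel_id)
    expect_identical(b$qc_pass, a$qc_pass)
    expect_equal(b$area_epi_mm2, a$area_epi_mm2, tolerance = 1e-9)
    expect_equal(b$area_tme_mm2, a$area_tme_mm2, tolerance = 1e-9)
    for (col in c("cell_id", "compartment", marker_names(a$cells)))
      expect_identical(b$cells[[col]], a$cells[[col]])
    expect_equal(b$cells$x_um, a$cells$x_um, tolerance = 1e-9)
    expect_equal(b$cells$y_um, a$cells$y_um, tolerance = 1e-9)
  }
  expect_equal(back$clinical, coh$clinical, tolerance = 1e-9)
})

test_that("write_results is deterministic, writes empty tables as header-only and lists every file", {
  tabs <- list(density = data.frame(patient = c("P1", "P2"), EPI.CD8T = c(1.5, 2)),
               empty = data.frame(a = character(), b = numeric()))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_results(tabs, d1)
  m2 <- write_results(tabs, d2)
  expect_setequal(m1$file, c("density.tsv", "empty.tsv"))
  expect_identical(readLines(file.path(d1, "empty.tsv")), "a\tb")
  for (f in m1$file)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("the same seed reproduces a byte-identical cohort on disk", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(sim_config(n_patients = 3), seed = 5), d1)
  write_cohort(simulate_cohort(sim_config(n_patients = 3), seed = 5), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})
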