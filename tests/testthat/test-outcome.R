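test_that("Kaplan-Meier with no censoring equals the empirical survivor function", {
  times <- c(3, 1, 7, 2, 9, 4, 8, 5, 10, 6)
  fit <- km_logrank(times, rep(1, 10), rep("all", 10))$fit
  expect_equal(fit$surv, 1 - seq_len(10) / 10)
  expect_equal(fit$time, sort(times))
})

test_that("the log-rank test is calibrated under the null and powered under HR 2", {
  set.seed(418)
  null_p <- replicate(200, {
    t <- rexp(60, 0.1); e <- rbinom(60, 1, 0.85)
    km_logrank(t, e, rep(c("a", "b"), 30))$p
  })
  expect_gt(mean(null_p < 0.05), 0.005)
  expect_lt(mean(null_p < 0.05), 0.11)
  expect_gt(suppressWarnings(stats::ks.test(null_p, "punif")$p.value), 0.001)
  power <- replicate(200, {
    t <- c(rexp(100, 0.05), rexp(100, 0.1))
    cens <- runif(200, 0, 60)
    km_logrank(pmin(t, cens), as.numeric(t <= cens), rep(c("a", "b"), each = 100))$p
  })
  expect_gt(mean(power < 0.05), 0.8)
})

test_that("Cox fits recover planted effects and refuse degenerate inputs", {
  set.seed(419)
  n <- 400
  x <- rnorm(n)
  t <- rexp(n, rate = 0.05 * exp(0.5 * x))
  cens <- runif(n, 0, 60)
  res <- cox_fit(pmin(t, cens), as.numeric(t <= cens), data.frame(x = x))
  expect_true(res$converged)
  expect_gt(res$hr, 0)
  expect_true(res$ci_lo < res$hr & res$hr < res$ci_hi)
  expect_true(log(res$ci_lo) < 0.5 & 0.5 < log(res$ci_hi))
  # multivariable mode reports every covariate of interest
  res2 <- cox_fit(pmin(t, cens), as.numeric(t <= cens),
                  data.frame(x = x, junk = rnorm(n)), mode = "multivariable")
  expect_setequal(res2$variable, c("x", "junk"))
  expect_error(cox_fit(t, rep(1, n), data.frame(k = rep(2, n))), "constant")
  expect_error(cox_fit(t, rep(0, n), data.frame(x = x)), "one event")
})

test_that("the Cox estimator's bias shrinks with sample size on exponential data", {
  set.seed(424)
  bias_at <- function(n, reps = 150) {
    mean(replicate(reps, {
      x <- rnorm(n)
      t <- rexp(n, rate = 0.05 * exp(0.7 * x))
      cens <- runif(n, 0, 80)
      fit <- cox_fit(pmin(t, cens), as.numeric(t <= cens), data.frame(x = x))
      log(fit$hr) - 0.7
    }))
  }
  b100 <- bias_at(100)
  b400 <- bias_at(400)
  expect_lt(abs(b400), 0.05)
  expect_lt(abs(b400), abs(b100) + 0.02)
})

test_that("contingency tests reproduce the reference clinical-table p-values", {
  # two-array baseline table rows (counts as printed) and the subtype table's
  # array row; 2x2 tables take the Yates correction, larger ones do not
  cases <- list(
    age = list(m = rbind(c(41, 38), c(49, 61)), p = 0.395),
    gender = list(m = rbind(c(42, 41), c(48, 58)), p = 0.562),
    diameter = list(m = rbind(c(45, 36), c(45, 63)), p = 0.081),
    n_stage = list(m = rbind(c(54, 52), c(24, 36), c(12, 12)), p = 0.384),
    m_stage = list(m = rbind(c(89, 95), c(1, 5)), p = 0.265),
    ajcc = list(m = rbind(c(12, 4), c(41, 47), c(36, 44), c(1, 5)), p = 0.061),
    os_event = list(m = rbind(c(49, 48), c(41, 52)), p = 0.458),
    subtype_array = list(m = rbind(c(19, 23, 13), c(36, 13, 12)), p = 0.02))
  for (nm in names(cases)) {
    res <- contingency_test(cases[[nm]]$m)
    digits <- nchar(sub("^[0-9]*\\.", "", as.character(cases[[nm]]$p)))
    expect_equal(round(res$p, digits), cases[[nm]]$p, label = nm)
    expect_equal(res$df, (nrow(cases[[nm]]$m) - 1) * (ncol(cases[[nm]]$m) - 1))
    expect_equal(res$yates, nrow(cases[[nm]]$m) == 2 && ncol(cases[[nm]]$m) == 2)
  }
})

test_that("2x2 tests equal the closed-form Yates statistic and handle degenerate tables", {
  set.seed(420)
  for (rep in 1:20) {
    m <- matrix(rpois(4, 30) + 1, 2, 2)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    yates <- sum((pmax(abs(m - e) - 0.5, 0))^2 / e)
    expect_equal(contingency_test(m)$statistic, yates)
  }
  flat <- contingency_test(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  expect_error(contingency_test(rbind(c(0, 0), c(5, 3))), "all-zero")
  expect_error(contingency_test(rbind(c(1.5, 2), c(3, 4))), "counts")
  expect_error(contingency_test(matrix(1:3, 1)), "2x2")
})

test_that("rank tests dispatch by group count and handle ties by convention", {
  x <- c(1, 2, 3, 4)
  expect_message(p_id <- rank_tests(c(x, x), rep(c("a", "b"), each = 4),
                                    paired = TRUE)$p, "convention")
  expect_equal(p_id, 1)
  expect_message(p_const <- rank_tests(rep(5, 10), rep(c("a", "b"), 5))$p,
                 "convention")
  expect_equal(p_const, 1)
  kw <- rank_tests(rnorm(30), rep(c("a", "b", "c"), 10))
  expect_match(kw$method, "Kruskal")
  expect_error(rank_tests(rnorm(30), rep(c("a", "b", "c"), 10), paired = TRUE),
               "two groups")
  set.seed(421)
  power <- replicate(200, {
    rank_tests(c(rnorm(50), rnorm(50, 1)), rep(c("a", "b"), each = 50))$p
  })
  expect_gt(mean(power < 0.05), 0.9)
  typeI <- replicate(200, {
    rank_tests(rnorm(60), rep(c("a", "b", "c"), 20))$p
  })
  expect_gt(mean(typeI < 0.05), 0.005)
  expect_lt(mean(typeI < 0.05), 0.11)
})

test_that("distance-stratified prognosis dichotomises per stratum and skips thin arms", {
  set.seed(422)
  n <- 60
  clin <- simulate_cohort(sim_config(n_patients = n, panels = "T",
                                     qc_fail_rate = c(M = 0, T = 0, O = 0),
                                     subtypes = NULL), seed = 423)$clinical
  ec <- data.frame(patient_id = clin$patient_id, phenotype = "CD8T",
                   within_20 = rpois(n, 20), beyond_30 = rpois(n, 5))
  res <- distance_stratified_prognosis(ec, clin)
  expect_setequal(res$stratum, c("within_20", "beyond_30"))
  expect_false(any(res$skipped))
  expect_true(all(res$hr > 0))
  expect_true(all(res$ci_lo <= res$hr & res$hr <= res$ci_hi))
  # constant counts leave one arm empty -> stratum is skipped, not dropped
  ec$within_20 <- 7L
  res2 <- distance_stratified_prognosis(ec, clin, strata = "within_20")
  expect_true(res2$skipped)
  expect_true(is.na(res2$hr))
})
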