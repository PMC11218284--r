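#' Kaplan-Meier curves with a log-rank test
#'
#' Product-limit survival estimates per group and the log-rank chi-squared
#' test of equality. With a single group only the curve is returned (no
#' test). Groups that are entirely censored still contribute their curve;
#' the test's degrees of freedom follow `survival::survdiff` (number of
#' groups represented minus one).
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param groups group labels (>= 2 non-empty groups for the test).
#' @return list of class `km_logrank`: `fit` (a `survfit`), `chisq`, `df`,
#'   `p`, `n`.
#' @export
km_logrank <- function(times, events, groups) {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  if (any(times < 0)) stop("negative survival times")
  if (any(!events %in% c(0, 1))) stop("events must be 0/1")
  groups <- factor(groups)
  if (any(table(groups) == 0L)) groups <- droplevels(groups)
  d <- data.frame(times = times, events = events, groups = groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups, data = d)
  if (nlevels(groups) < 2L)
    return(structure(list(fit = fit, chisq = NA_real_, df = 0L, p = NA_real_,
                          n = length(times)), class = "km_logrank"))
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups, data = d)
  df <- length(sd$n) - 1L
  structure(list(fit = fit, chisq = unname(sd$chisq), df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 n = length(times)),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("<km_logrank> n=%d  chisq=%.3f on %d df  p=%.4g\n",
              x$n, x$chisq, x$df, x$p))
  invisible(x)
}

#' Cox proportional-hazards fits
#'
#' Partial-likelihood estimates with Wald confidence intervals and p-values.
#' In univariate mode each covariate column is fitted in its own model
#' (optionally adjusted for the `adjusters` columns, as in a multivariable
#' forest plot); in multivariable mode all covariate columns enter one
#' model. Non-convergence is flagged in the result, never silent.
#'
#' @param times,events follow-up and 0/1 event indicator.
#' @param covariates data frame of covariates of interest (numeric or
#'   factor).
#' @param adjusters optional data frame of adjustment covariates.
#' @param mode `"univariate"` (one model per covariate column) or
#'   `"multivariable"` (all columns jointly).
#' @param conf_level confidence level for the hazard-ratio interval.
#' @return data frame of class `survival_result`: `variable`, `n`, `events`,
#'   `hr`, `ci_lo`, `ci_hi`, `p`, `converged`.
#' @export
cox_fit <- function(times, events, covariates, adjusters = NULL,
                    mode = c("univariate", "multivariable"),
                    conf_level = 0.95) {
  mode <- match.arg(mode)
  covariates <- as.data.frame(covariates)
  if (sum(events) < 1) stop("need at least one event")
  constant <- vapply(covariates, function(v) length(unique(v)) < 2L, logical(1L))
  if (any(constant))
    stop("constant covariate(s): ", paste(names(covariates)[constant], collapse = ", "))
  fit_extract <- function(dat, wanted) {
    converged <- TRUE
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(times, events) ~ ., data = dat),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    s <- summary(fit, conf.int = conf_level)
    co <- s$coefficients
    ci <- s$conf.int
    rows <- unlist(lapply(wanted, function(v)
      grep(paste0("^", gsub("([^[:alnum:]_.])", "\\\\\\1", v)), rownames(co))))
    data.frame(variable = rownames(co)[rows], n = s$n, events = s$nevent,
               hr = unname(co[rows, "exp(coef)"]),
               ci_lo = unname(ci[rows, 3L]), ci_hi = unname(ci[rows, 4L]),
               p = unname(co[rows, "Pr(>|z|)"]),
               converged = converged, stringsAsFactors = FALSE)
  }
  out <- if (mode == "univariate") {
    do.call(rbind, lapply(names(covariates), function(v) {
      dat <- covariates[v]
      if (!is.null(adjusters)) dat <- cbind(dat, adjusters)
      fit_extract(dat, v)
    }))
  } else {
    dat <- covariates
    if (!is.null(adjusters)) dat <- cbind(dat, adjusters)
    fit_extract(dat, names(covariates))
  }
  rownames(out) <- NULL
  class(out) <- c("survival_result", "data.frame")
  out
}

#' Distance-stratified prognosis of effective immune cells
#'
#' For each phenotype and distance stratum (cumulative effective counts
#' within each radius and the beyond-the-largest-radius remainder), patients
#' are dichotomised at the cohort median count (high = above the median) and
#' compared by Kaplan-Meier/log-rank and a univariate Cox model (high vs
#' low). Strata with fewer than `min_per_arm` patients in either arm are
#' skipped with a log entry in the output.
#'
#' @param effective_counts result of [effective_count_matrix()].
#' @param clinical validated clinical table (supplies `os_months`,
#'   `os_event`).
#' @param strata count columns to stratify on (default: every `within_*` and
#'   `beyond_*` column present).
#' @param min_per_arm minimum patients per arm.
#' @param missing_as_zero treat patients without a row for a phenotype as
#'   zero-count patients (they had no such cells) rather than dropping them.
#' @return data frame: `phenotype`, `stratum`, `n`, `n_high`, `hr`, `ci_lo`,
#'   `ci_hi`, `p_cox`, `p_logrank`, `skipped`.
#' @export
distance_stratified_prognosis <- function(effective_counts, clinical,
                                          strata = NULL, min_per_arm = 2L,
                                          missing_as_zero = TRUE) {
  clinical <- validate_clinical_table(clinical)
  count_cols <- grep("^(within|beyond)_", names(effective_counts), value = TRUE)
  if (is.null(strata)) strata <- count_cols
  stopifnot(all(strata %in% count_cols))
  rows <- list()
  for (ph in sort(unique(effective_counts$phenotype))) {
    sub <- effective_counts[effective_counts$phenotype == ph, ]
    for (st in strata) {
      x <- sub[[st]][match(clinical$patient_id, sub$patient_id)]
      if (missing_as_zero) x[is.na(x)] <- 0L
      keep <- !is.na(x)
      xx <- x[keep]
      cl <- clinical[keep, ]
      high <- xx > stats::median(xx)
      row <- data.frame(phenotype = ph, stratum = st, n = length(xx),
                        n_high = sum(high), hr = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, p_cox = NA_real_,
                        p_logrank = NA_real_, skipped = FALSE,
                        stringsAsFactors = FALSE)
      if (sum(high) < min_per_arm || sum(!high) < min_per_arm) {
        row$skipped <- TRUE
      } else {
        lr <- km_logrank(cl$os_months, cl$os_event, high)
        cx <- cox_fit(cl$os_months, cl$os_event,
                      data.frame(high = as.numeric(high)))
        row$hr <- cx$hr; row$ci_lo <- cx$ci_lo; row$ci_hi <- cx$ci_hi
        row$p_cox <- cx$p; row$p_logrank <- lr$p
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chi-squared contingency test
#'
#' Pearson chi-squared test of independence on a table of counts, with the
#' Yates continuity correction applied exactly when the table is 2x2 (the
#' convention behind clinical baseline-characteristics tables). Degrees of
#' freedom are (r-1)(c-1). Tables with an all-zero row or column are
#' rejected (expected counts undefined).
#'
#' @param tab non-negative integer matrix, at least 2x2.
#' @return list of class `contingency_result`: `observed`, `statistic`,
#'   `df`, `p`, `yates`.
#' @export
contingency_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2x2")
  if (any(tab < 0) || any(tab != round(tab))) stop("table must hold non-negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has an all-zero row or column; expected counts undefined")
  yates <- nrow(tab) == 2L && ncol(tab) == 2L
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  structure(list(observed = tab, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value, yates = yates),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> X-squared=%.4f on %d df, p=%.4g%s\n",
              x$statistic, x$df, x$p,
              if (x$yates) " (Yates-corrected)" else ""))
  invisible(x)
}

#' Rank-based group comparisons
#'
#' Two groups: Wilcoxon rank-sum (signed-rank when `paired = TRUE`); more
#' than two groups: Kruskal-Wallis. All-tied (constant) data returns p = 1
#' by convention with a message rather than failing.
#'
#' @param values numeric measurements.
#' @param groups group labels (two or more groups).
#' @param paired logical; paired mode requires exactly two groups of equal
#'   size in matching order.
#' @return list: `p`, `method`, `statistic`.
#' @export
rank_tests <- function(values, groups, paired = FALSE) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least two groups")
  if (length(unique(values)) == 1L) {
    message("rank_tests: all values tied; returning p = 1 by convention")
    return(list(p = 1, method = "degenerate (all tied)", statistic = NA_real_))
  }
  if (k == 2L) {
    a <- values[groups == levels(groups)[1L]]
    b <- values[groups == levels(groups)[2L]]
    if (paired) {
      if (length(a) != length(b)) stop("paired mode requires equal-length groups")
      if (all(a == b)) {
        message("rank_tests: identical paired vectors; returning p = 1 by convention")
        return(list(p = 1, method = "Wilcoxon signed rank (degenerate)",
                    statistic = NA_real_))
      }
      wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE))
    } else {
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    }
    list(p = wt$p.value, method = wt$method, statistic = unname(wt$statistic))
  } else {
    if (paired) stop("paired mode supports exactly two groups")
    kt <- stats::kruskal.test(values, groups)
    list(p = kt$p.value, method = kt$method, statistic = unname(kt$statistic))
  }
}
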