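#' Cluster patients into immune subtypes
#'
#' Agglomerative hierarchical clustering (Ward variance criterion,
#' `ward.D2`) on Euclidean distances of the density matrix, with the cluster
#' number chosen over `k_range` by average silhouette width (the elbow
#' within-cluster sums are reported as a diagnostic; when the two disagree,
#' silhouette wins). Columns are z-scored by default so the partition is
#' invariant to per-phenotype affine rescaling; the result is deterministic
#' and invariant to patient and column order. Cluster labels are
#' canonicalised (`C1` = largest cluster, ties broken by smallest patient
#' id) so they are stable under row permutation.
#'
#' @param density_matrix numeric matrix/data frame, rows = patients (rownames
#'   required), columns = (compartment, phenotype) densities; must be
#'   complete (drop or impute missing values upstream).
#' @param k_range candidate cluster numbers, within `[2, n-1]`.
#' @param scale z-score columns before clustering.
#' @return list of class `subtype_assignment`: `labels` (named character),
#'   `k`, `hclust`, `diagnostics` (k, avg_silhouette, wss).
#' @export
cluster_patients <- function(density_matrix, k_range = 2:6, scale = TRUE) {
  x <- as.matrix(density_matrix)
  if (is.null(rownames(x))) stop("density matrix must have patient rownames")
  if (anyNA(x)) stop("density matrix has missing values; drop or impute upstream")
  keep <- apply(x, 2L, stats::sd) > 0
  if (!any(keep)) stop("degenerate input: all density columns are constant")
  x <- x[, keep, drop = FALSE]
  if (scale) x <- base::scale(x)
  x <- x[, order(colnames(x)), drop = FALSE]  # column-order invariance
  ord <- order(rownames(x))
  x <- x[ord, , drop = FALSE]                 # row-order invariance
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L | k_range > n - 1L))
    stop("k_range must lie within [2, n-1]")
  d <- stats::dist(x)
  hc <- stats::hclust(d, method = "ward.D2")
  diag_rows <- lapply(k_range, function(k) {
    lab <- stats::cutree(hc, k = k)
    sil <- mean(cluster::silhouette(lab, d)[, "sil_width"])
    wss <- sum(vapply(split(seq_len(n), lab), function(i) {
      xi <- x[i, , drop = FALSE]
      sum(sweep(xi, 2L, colMeans(xi))^2)
    }, numeric(1L)))
    data.frame(k = k, avg_silhouette = sil, wss = wss)
  })
  diagnostics <- do.call(rbind, diag_rows)
  k_best <- diagnostics$k[which.max(diagnostics$avg_silhouette)]
  raw <- stats::cutree(hc, k = k_best)
  labels <- canonical_labels(raw)
  structure(list(labels = labels, k = k_best, hclust = hc,
                 diagnostics = diagnostics),
            class = "subtype_assignment")
}

# Relabel clusters C1..Ck by decreasing size (ties: smallest member id).
canonical_labels <- function(raw) {
  sizes <- table(raw)
  first_member <- vapply(names(sizes), function(g)
    min(names(raw)[raw == g]), character(1L))
  ord <- order(-as.integer(sizes), first_member)
  map <- stats::setNames(paste0("C", seq_along(ord)), names(sizes)[ord])
  stats::setNames(unname(map[as.character(raw)]), names(raw))
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat(sprintf("<subtype_assignment> k=%d over %d patients: %s\n", x$k,
              length(x$labels),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = " ")))
  invisible(x)
}

#' Phenotype-phenotype correlation matrix
#'
#' Pairwise correlation of density columns across patients. Spearman by
#' default (densities are heavy-tailed); zero-variance phenotypes yield `NA`
#' coefficients rather than 0. The result is symmetric with unit diagonal.
#'
#' @param density_matrix rows = patients, columns = phenotype densities
#'   (>= 3 patients).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return correlation matrix with attribute `"method"`.
#' @export
phenotype_correlation <- function(density_matrix,
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- as.matrix(density_matrix)
  if (nrow(x) < 3L) stop("need at least 3 patients for correlation")
  cm <- suppressWarnings(stats::cor(x, method = method,
                                    use = "pairwise.complete.obs"))
  zero_var <- apply(x, 2L, function(v) stats::sd(v, na.rm = TRUE) == 0)
  cm[zero_var, ] <- NA_real_
  cm[, zero_var] <- NA_real_
  diag(cm) <- 1
  attr(cm, "method") <- method
  cm
}

#' Differential densities between two patient groups
#'
#' Per phenotype: log2 fold change of group mean densities (with pseudocount
#' epsilon = half the smallest nonzero density applied to zero means) and a
#' Wilcoxon rank-sum p-value; a phenotype is flagged when |log2FC| > 1 and
#' p < 0.05 (no multiple-testing correction — the flags are a screening
#' cut-off, not FDR-controlled inference).
#'
#' @param density_matrix rows = patients (rownames required).
#' @param group_a,group_b disjoint, non-empty patient id vectors.
#' @return data frame: `phenotype`, `mean_a`, `mean_b`, `log2_fc`, `p`,
#'   `significant`.
#' @export
differential_densities <- function(density_matrix, group_a, group_b) {
  x <- as.matrix(density_matrix)
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  missing <- setdiff(c(group_a, group_b), rownames(x))
  if (length(missing))
    stop("patients absent from density matrix: ", paste(missing, collapse = ", "))
  eps <- {
    nz <- x[x > 0]
    if (length(nz)) min(nz) / 2 else 1
  }
  rows <- lapply(colnames(x), function(ph) {
    a <- x[group_a, ph]; b <- x[group_b, ph]
    ma <- mean(a); mb <- mean(b)
    lfc <- log2((ma + eps * (ma == 0)) / (mb + eps * (mb == 0)))
    p <- if (length(unique(c(a, b))) == 1L) 1 else
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    data.frame(phenotype = ph, mean_a = ma, mean_b = mb, log2_fc = lfc,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- abs(out$log2_fc) > 1 & out$p < 0.05
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items
#' (1 = identical partitions, ~0 = random agreement). Used to score recovery
#' of planted subtype structure.
#'
#' @param a,b label vectors of equal length.
#' @return adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
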