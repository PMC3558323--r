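# Transcriptomic signature of high-instability tumors: per-probe Welch
# t-tests between the grade-3 group and the rest on RMA-style log2
# expression, selection on raw p-values (no multiplicity correction by
# default, matching the derivation rule), hierarchical clustering on the
# signature and nearest-centroid application to new cohorts.

check_expr <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort("expr must be a numeric matrix (probes x samples)")
  }
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr))) {
    abort("expr needs unique probe_id rownames")
  }
  if (is.null(colnames(expr))) abort("expr needs sample_id colnames")
  invisible(expr)
}

#' Welch t-test signature derivation
#'
#' Per-probe two-sided Welch t-test (unequal variances, Satterthwaite
#' degrees of freedom) between the focal group and the rest; probes with
#' raw `p < p_threshold` form the signature.  Probes with zero variance in
#' both groups are skipped with a warning.  Optionally the p-values can be
#' Benjamini-Hochberg adjusted before thresholding (off by default,
#' matching the raw-p derivation rule).
#'
#' @param expr Numeric matrix, probes x samples, log2 scale.
#' @param labels Logical or two-level vector over the columns of `expr`;
#'   `TRUE` (or the first level) marks the focal group.
#' @param p_threshold Selection threshold on the p-value (default 5e-3).
#' @param adjust Apply BH adjustment before thresholding (default FALSE).
#' @return A tibble with one row per tested probe: `probe_id`,
#'   `mean_difference` (focal minus rest), `statistic`, `df`, `p.value`,
#'   `selected`.
#' @export
welch_t_signature <- function(expr, labels, p_threshold = 5e-3, adjust = FALSE) {
  check_expr(expr)
  if (length(labels) != ncol(expr)) abort("labels must have one entry per sample")
  if (is.logical(labels)) {
    focal <- labels
  } else {
    lev <- unique(as.character(labels))
    if (length(lev) != 2) abort("labels must define exactly two groups")
    focal <- as.character(labels) == lev[1]
  }
  n1 <- sum(focal)
  n2 <- sum(!focal)
  if (n1 < 2 || n2 < 2) abort("Each group needs at least 2 samples")
  x1 <- expr[, focal, drop = FALSE]
  x2 <- expr[, !focal, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  degenerate <- v1 == 0 & v2 == 0
  if (any(degenerate)) {
    warn(sprintf("Skipping %d probe(s) with zero variance in both groups", sum(degenerate)))
  }
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * pt(-abs(t_stat), df)
  out <- tibble(
    probe_id = rownames(expr),
    mean_difference = unname(m1 - m2),
    statistic = unname(t_stat),
    df = unname(df),
    p.value = unname(p)
  )[!degenerate, ]
  crit <- if (adjust) stats::p.adjust(out$p.value, "BH") else out$p.value
  out$selected <- crit < p_threshold
  out
}

#' Class centroids on a probe signature
#'
#' @param expr Numeric matrix, probes x samples.
#' @param labels Group label per sample.
#' @param signature Character vector of probe ids.
#' @return A matrix signature-probes x classes of per-class mean expression.
#' @export
signature_centroids <- function(expr, labels, signature) {
  check_expr(expr)
  signature <- intersect(signature, rownames(expr))
  if (length(signature) == 0) abort("Empty signature")
  sub <- expr[signature, , drop = FALSE]
  classes <- unique(as.character(labels))
  vapply(classes, function(cl) {
    rowMeans(sub[, as.character(labels) == cl, drop = FALSE])
  }, numeric(length(signature)))
}

#' Cluster samples on a signature
#'
#' Hierarchical clustering (same engine as the genomic profile clustering:
#' 1 - Pearson distance, Ward linkage) of samples restricted to the
#' signature probes.  A constant matrix yields an arbitrary but
#' deterministic split, with a warning.
#'
#' @param expr Numeric matrix, probes x samples.
#' @param signature Character vector of probe ids (non-empty intersection
#'   with `expr` required).
#' @param k Number of groups (default 2).
#' @param linkage Linkage method (default `"ward.D2"`).
#' @return A `g2i_clusters` object (see [agglomerative_cluster()]).
#' @export
cluster_by_signature <- function(expr, signature, k = 2L, linkage = "ward.D2") {
  check_expr(expr)
  signature <- intersect(signature, rownames(expr))
  if (length(signature) == 0) abort("Empty signature")
  sub <- expr[signature, , drop = FALSE]
  suppressWarnings(r <- cor(sub))
  d <- 1 - r
  if (anyNA(d)) {
    warn("Constant expression column(s): undefined correlations set to distance 1")
    const <- apply(sub, 2, function(x) all(x == x[1]))
    for (i in which(const)) {
      for (j in seq_len(ncol(sub))) {
        if (i == j) next
        same <- const[j] && identical(sub[, i], sub[, j])
        d[i, j] <- d[j, i] <- if (same) 0 else 1
      }
    }
    d[is.na(d)] <- 1
  }
  diag(d) <- 0
  agglomerative_cluster(as.dist(d), k = k, linkage = linkage)
}

#' Nearest-centroid classification of new samples
#'
#' Each new sample is assigned the class whose centroid it correlates with
#' best (Pearson, on the probes shared between the new matrix and the
#' centroids).  At least half of the signature probes must be present;
#' exact correlation ties (or undefined correlations) give
#' `"unclassified"`.
#'
#' @param expr_new Numeric matrix, probes x samples.
#' @param centroids Matrix from [signature_centroids()].
#' @return A tibble with `sample_id`, `class`, `correlation`.
#' @export
centroid_classify <- function(expr_new, centroids) {
  check_expr(expr_new)
  shared <- intersect(rownames(expr_new), rownames(centroids))
  if (length(shared) < 0.5 * nrow(centroids)) {
    abort("Fewer than 50% of signature probes present in the new matrix")
  }
  sub <- expr_new[shared, , drop = FALSE]
  cen <- centroids[shared, , drop = FALSE]
  suppressWarnings(r <- cor(sub, cen))
  cls <- character(ncol(sub))
  best <- numeric(ncol(sub))
  for (i in seq_len(ncol(sub))) {
    ri <- r[i, ]
    if (anyNA(ri)) {
      cls[i] <- "unclassified"
      best[i] <- NA_real_
      next
    }
    top <- which(ri >= max(ri) - 1e-12)
    if (length(top) > 1) {
      cls[i] <- "unclassified"
      best[i] <- max(ri)
    } else {
      cls[i] <- colnames(cen)[top]
      best[i] <- ri[top]
    }
  }
  tibble(sample_id = colnames(sub), class = cls, correlation = best)
}
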