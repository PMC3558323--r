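# Unsupervised clustering of GNL profiles into genomic archetype groups,
# plus per-group recurrence and between-group differential screens.

gnl_status_matrix <- function(gnl, clone_map) {
  m <- match(gnl$clone_id, clone_map$clone_id)
  if (anyNA(m)) abort("gnl contains clone_ids absent from the clone map")
  samples <- unique(gnl$sample_id)
  mat <- matrix(NA_real_, nrow = nrow(clone_map), ncol = length(samples),
    dimnames = list(clone_map$clone_id, samples)
  )
  mat[cbind(m, match(gnl$sample_id, samples))] <- gnl$status
  mat
}

#' Pairwise distance between GNL profiles
#'
#' Default distance is 1 - Pearson correlation between per-clone status
#' vectors, with missing clones excluded pairwise.  A constant (e.g.
#' all-normal) profile has no defined correlation: a pair of identical
#' constant profiles is given distance 0, and any other pair involving a
#' constant profile distance 1, with a warning.  The `"manhattan"` option
#' uses the mean absolute status difference instead.
#'
#' @param gnl Long tibble with `sample_id`, `clone_id`, `status`.
#' @param clone_map Clone map the profiles share.
#' @param method `"pearson"` (default) or `"manhattan"`.
#' @return A symmetric [stats::dist] object over samples.
#' @export
gnl_distance <- function(gnl, clone_map, method = c("pearson", "manhattan")) {
  method <- match.arg(method)
  mat <- gnl_status_matrix(gnl, clone_map)
  if (ncol(mat) < 2) abort("Need at least 2 profiles to compute distances")
  if (method == "manhattan") {
    d <- as.matrix(stats::dist(t(mat), method = "manhattan")) / nrow(mat)
  } else {
    suppressWarnings(r <- cor(mat, use = "pairwise.complete.obs"))
    d <- 1 - r
    if (anyNA(d)) {
      warn("Constant profile(s): undefined correlations set to distance 1")
      const <- apply(mat, 2, function(x) {
        x <- x[!is.na(x)]
        length(x) == 0 || all(x == x[1])
      })
      for (i in which(const)) {
        for (j in seq_len(ncol(mat))) {
          if (i == j) next
          same <- const[j] && identical(mat[, i], mat[, j])
          d[i, j] <- d[j, i] <- if (same) 0 else 1
        }
      }
      d[is.na(d)] <- 1
    }
    diag(d) <- 0
  }
  as.dist(d)
}

#' Agglomerative clustering of genomic profiles
#'
#' Ward-linkage (`ward.D2`) hierarchical clustering of a profile distance
#' matrix, cut into `k` groups.  The default k = 6 follows the archetype
#' structure of breast-tumor aCGH cohorts; it is a free parameter with no
#' automatic selection.
#'
#' @param distances A [stats::dist] object (e.g. from [gnl_distance()]).
#' @param k Number of clusters (1 <= k <= number of samples).
#' @param linkage Linkage method passed to [stats::hclust()]
#'   (default `"ward.D2"`; `"average"` is the common alternative).
#' @return An object of class `g2i_clusters` with the sample-to-cluster
#'   assignment and the dendrogram merge history; see [tidy()], [glance()]
#'   and [autoplot()] methods.
#' @export
agglomerative_cluster <- function(distances, k = 6L, linkage = "ward.D2") {
  if (!inherits(distances, "dist")) abort("distances must be a dist object")
  n <- attr(distances, "Size")
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n) abort("k must lie between 1 and the number of samples")
  hc <- hclust(distances, method = linkage)
  cluster <- cutree(hc, k = k)
  structure(
    list(
      assignment = tibble(
        sample_id = labels(distances) %||% as.character(seq_len(n)),
        cluster = as.integer(cluster)
      ),
      hclust = hc,
      k = k,
      linkage = linkage,
      distances = distances
    ),
    class = "g2i_clusters"
  )
}

#' Cluster GNL profiles
#'
#' Convenience wrapper: [gnl_distance()] then [agglomerative_cluster()].
#'
#' @inheritParams gnl_distance
#' @inheritParams agglomerative_cluster
#' @export
cluster_gnl <- function(gnl, clone_map, k = 6L, method = "pearson",
                        linkage = "ward.D2") {
  agglomerative_cluster(gnl_distance(gnl, clone_map, method = method),
    k = k, linkage = linkage
  )
}

#' @export
print.g2i_clusters <- function(x, ...) {
  sizes <- table(x$assignment$cluster)
  cat(sprintf(
    "Agglomerative clustering (%s linkage), %d samples in %d clusters\n",
    x$linkage, nrow(x$assignment), x$k
  ))
  cat("Cluster sizes:", paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Per-clone gain and loss frequencies of a group of profiles
#'
#' @param gnl Long tibble with `sample_id`, `clone_id`, `status` for the
#'   group (subset before calling, or pass `groups` to stratify).
#' @param clone_map Clone map the profiles share.
#' @param groups Optional named vector mapping sample_id to a group label;
#'   when given, frequencies are computed per group.
#' @return A tibble with `clone_id`, `chromosome`, `gain_frac`, `loss_frac`
#'   (and `group` when stratified); fractions are over non-missing clones.
#' @export
frequency_profile <- function(gnl, clone_map, groups = NULL) {
  if (nrow(gnl) == 0) abort("Empty group of profiles")
  gnl$.group <- if (is.null(groups)) "all" else {
    as.character(groups[gnl$sample_id])
  }
  out <- gnl %>%
    filter(!is.na(.data$.group)) %>%
    group_by(.data$.group, .data$clone_id) %>%
    summarise(
      gain_frac = mean(.data$status == 1L, na.rm = TRUE),
      loss_frac = mean(.data$status == -1L, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(
      chromosome = clone_map$chromosome[match(.data$clone_id, clone_map$clone_id)],
      .order = match(.data$clone_id, clone_map$clone_id)
    ) %>%
    arrange(.data$.group, .data$.order) %>%
    select(-".order") %>%
    rename(group = ".group")
  out$gain_frac[is.nan(out$gain_frac)] <- 0
  out$loss_frac[is.nan(out$loss_frac)] <- 0
  if (is.null(groups)) out$group <- NULL
  out
}

# Maximal runs of TRUE within chromosomes of a clone map.
clone_runs <- function(pass, clone_map) {
  res <- list()
  for (idx in split(seq_len(nrow(clone_map)), chrom_rank(clone_map$chromosome))) {
    r <- rle(pass[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    for (i in keep) {
      res[[length(res) + 1]] <- tibble(
        chromosome = clone_map$chromosome[idx[1]],
        first_clone = clone_map$clone_id[idx[starts[i]]],
        last_clone = clone_map$clone_id[idx[ends[i]]],
        first_index = idx[starts[i]],
        last_index = idx[ends[i]],
        n_clones = ends[i] - starts[i] + 1L
      )
    }
  }
  if (length(res) == 0) {
    return(tibble(
      chromosome = character(), first_clone = character(),
      last_clone = character(), first_index = integer(),
      last_index = integer(), n_clones = integer()
    ))
  }
  bind_rows(res)
}

#' Recurrently altered regions of a frequency profile
#'
#' Maximal runs of clones whose gain (or loss) fraction strictly exceeds
#' `threshold`.
#'
#' @param freq A [frequency_profile()] tibble (single group).
#' @param clone_map Clone map the frequencies are aligned to.
#' @param threshold Frequency cut-off in (0, 1].
#' @return A tibble of runs with `direction` (`"gain"`/`"loss"`),
#'   chromosome, clone span and length.
#' @export
recurrent_regions <- function(freq, clone_map, threshold = 0.8) {
  if (!(threshold > 0 && threshold <= 1)) abort("threshold must lie in (0, 1]")
  out <- list()
  for (dir in c("gain", "loss")) {
    fr <- freq[[paste0(dir, "_frac")]][match(clone_map$clone_id, freq$clone_id)]
    fr[is.na(fr)] <- 0
    runs <- clone_runs(fr > threshold, clone_map)
    if (nrow(runs) > 0) {
      runs$direction <- dir
      out[[dir]] <- runs
    }
  }
  if (length(out) == 0) {
    empty <- clone_runs(logical(nrow(clone_map)), clone_map)
    empty$direction <- character(0)
    return(empty)
  }
  bind_rows(out) %>% arrange(chrom_rank(.data$chromosome), .data$first_index)
}

#' Regions differentially altered between two groups
#'
#' Per clone and direction (gain, loss), a Fisher exact test of
#' altered-in-that-direction versus not between the two groups.  Clones in
#' the focal group passing both the raw p-value filter (`p <= p_max`) and
#' the frequency filter (`freq >= freq_min` in the focal group) are merged
#' into maximal runs.  No multiplicity correction is applied; the screen is
#' a filter, not an inference, and raw p-values are reported.
#'
#' @param gnl Long tibble with `sample_id`, `clone_id`, `status`.
#' @param clone_map Clone map the profiles share.
#' @param groups Named vector mapping sample_id to exactly two group labels.
#' @param focal Label of the focal group (default: first level).
#' @param p_max Raw Fisher p-value cut-off (default 1e-4).
#' @param freq_min Minimum alteration frequency in the focal group
#'   (default 0.5).
#' @return A tibble of runs with direction, chromosome, clone span, the
#'   worst (largest) p and the smallest focal frequency within the run.
#' @export
differential_regions <- function(gnl, clone_map, groups, focal = NULL,
                                 p_max = 1e-4, freq_min = 0.5) {
  groups <- groups[!is.na(groups)]
  lev <- unique(as.character(groups))
  if (length(lev) != 2) abort("groups must define exactly two groups")
  focal <- focal %||% lev[1]
  if (!focal %in% lev) abort("focal must be one of the group labels")
  other <- setdiff(lev, focal)
  if (min(table(groups)) < 2) abort("Each group needs at least 2 samples")
  mat <- gnl_status_matrix(gnl, clone_map)
  mat <- mat[, colnames(mat) %in% names(groups), drop = FALSE]
  in_focal <- as.character(groups[colnames(mat)]) == focal
  out <- list()
  for (dir in c("gain", "loss")) {
    alt <- mat == (if (dir == "gain") 1 else -1)
    k1 <- rowSums(alt[, in_focal, drop = FALSE], na.rm = TRUE)
    n1 <- rowSums(!is.na(alt[, in_focal, drop = FALSE]))
    k2 <- rowSums(alt[, !in_focal, drop = FALSE], na.rm = TRUE)
    n2 <- rowSums(!is.na(alt[, !in_focal, drop = FALSE]))
    freq1 <- ifelse(n1 > 0, k1 / n1, 0)
    pvals <- rep(1, nrow(mat))
    test_idx <- which(freq1 >= freq_min & n1 > 0 & n2 > 0)
    for (i in test_idx) {
      tab <- matrix(c(k1[i], n1[i] - k1[i], k2[i], n2[i] - k2[i]), nrow = 2)
      pvals[i] <- fisher.test(tab)$p.value
    }
    pass <- freq1 >= freq_min & pvals <= p_max
    runs <- clone_runs(pass, clone_map)
    if (nrow(runs) > 0) {
      runs$direction <- dir
      runs$max_p <- vapply(seq_len(nrow(runs)), function(i) {
        max(pvals[runs$first_index[i]:runs$last_index[i]])
      }, numeric(1))
      runs$min_freq <- vapply(seq_len(nrow(runs)), function(i) {
        min(freq1[runs$first_index[i]:runs$last_index[i]])
      }, numeric(1))
      out[[dir]] <- runs
    }
  }
  if (length(out) == 0) {
    empty <- clone_runs(logical(nrow(clone_map)), clone_map)
    empty$direction <- character(0)
    empty$max_p <- numeric(0)
    empty$min_freq <- numeric(0)
    return(empty)
  }
  bind_rows(out) %>% arrange(chrom_rank(.data$chromosome), .data$first_index)
}
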