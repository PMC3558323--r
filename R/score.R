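# The two-parameter genomic instability index (G2I).
#
# A — the overall level of genomic alteration: for each autosomal chromosome
#     arm, the proportion of clones called gained or lost, averaged over arms
#     without weighting.
# N — the number of altered genomic regions: maximal runs of non-normal
#     status, counted per chromosome and summed over the autosomes.  Runs
#     never span chromosomes; a gain run next to a loss run counts as two
#     regions.  Before counting, a "local score" smoothing pass removes
#     short status islands that would otherwise inflate the breakpoint count.

#' Local-score smoothing of a GNL status vector
#'
#' Iteratively reassigns any maximal run shorter than `min_run` whose two
#' flanking runs (same chromosome, no large missing-data gap between) agree
#' on a status, until a fixed point is reached.  Runs at chromosome ends and
#' runs whose flanks disagree are left unchanged, as are runs at least
#' `min_run` long.  The operation is idempotent and never increases the
#' number of altered regions.
#'
#' @param status Integer vector in {-1, 0, 1} (NA = missing clone) for a
#'   single chromosome, in genome order.
#' @param min_run Minimum run length that is immune to reassignment
#'   (default 2: only isolated single clones are absorbed).
#' @return The smoothed status vector.
#' @export
#' @examples
#' local_score_smooth(c(1L, 1L, 0L, 1L, 1L), min_run = 2)
local_score_smooth <- function(status, min_run = 2L) {
  min_run <- as.integer(min_run)
  if (is.na(min_run) || min_run < 1L) abort("min_run must be >= 1")
  repeat {
    runs <- status_runs(status)
    changed <- FALSE
    if (nrow(runs) >= 3) {
      for (i in 2:(nrow(runs) - 1L)) {
        if (runs$length[i] < min_run &&
          runs$block[i - 1L] == runs$block[i] &&
          runs$block[i + 1L] == runs$block[i] &&
          runs$status[i - 1L] == runs$status[i + 1L] &&
          runs$status[i - 1L] != runs$status[i]) {
          idx <- runs$start[i]:runs$end[i]
          status[idx][!is.na(status[idx])] <- runs$status[i - 1L]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  status
}

#' Local-score smoothing of GNL profiles
#'
#' Applies [local_score_smooth()] per sample and chromosome.
#'
#' @param gnl Long tibble with `sample_id`, `clone_id`, `status`.
#' @param clone_map Clone map the profiles are aligned to.
#' @param min_run Passed to [local_score_smooth()].
#' @return `gnl` with the `status` column smoothed.
#' @export
smooth_gnl <- function(gnl, clone_map, min_run = 2L) {
  chrom <- clone_map$chromosome[match(gnl$clone_id, clone_map$clone_id)]
  if (anyNA(chrom)) abort("gnl contains clone_ids absent from the clone map")
  for (rows_s in split(seq_len(nrow(gnl)), gnl$sample_id)) {
    for (idx in split(rows_s, chrom_rank(chrom[rows_s]))) {
      gnl$status[idx] <- local_score_smooth(gnl$status[idx], min_run = min_run)
    }
  }
  gnl
}

#' Overall level of genomic alteration (A)
#'
#' The unweighted mean over autosomal chromosome arms of the proportion of
#' clones with non-normal status.  Arms without any usable (non-missing)
#' clone are dropped from the average with a warning.
#'
#' @param gnl Long tibble with `sample_id`, `clone_id`, `status`.
#' @param clone_map Clone map with an `arm` column (see [assign_arms()]).
#' @return A tibble with `sample_id`, `A`.
#' @export
fraction_genome_altered <- function(gnl, clone_map) {
  if (!"arm" %in% names(clone_map)) {
    abort("clone_map needs an arm column; run assign_arms() first")
  }
  m <- match(gnl$clone_id, clone_map$clone_id)
  gnl$.chrom <- clone_map$chromosome[m]
  gnl$.arm <- clone_map$arm[m]
  per_arm <- gnl %>%
    filter(is_autosome(.data$.chrom)) %>%
    group_by(.data$sample_id, .data$.chrom, .data$.arm) %>%
    summarise(
      prop = mean(.data$status != 0, na.rm = TRUE),
      usable = sum(!is.na(.data$status)),
      .groups = "drop"
    )
  if (any(per_arm$usable == 0)) {
    warn("Dropping chromosome arm(s) with no usable clones from the A average")
    per_arm <- per_arm[per_arm$usable > 0, ]
  }
  per_arm %>%
    group_by(.data$sample_id) %>%
    summarise(A = mean(.data$prop), .groups = "drop")
}

#' Number of altered genomic regions (N)
#'
#' Counts maximal runs of non-normal status per autosome and sums them.
#' Profiles should be local-score smoothed first (see [smooth_gnl()]); the
#' count is over whatever statuses are passed in.
#'
#' @inheritParams fraction_genome_altered
#' @return A tibble with `sample_id`, `N` (integer).
#' @export
count_altered_regions <- function(gnl, clone_map) {
  chrom <- clone_map$chromosome[match(gnl$clone_id, clone_map$clone_id)]
  out <- lapply(split(seq_len(nrow(gnl)), gnl$sample_id), function(rows_s) {
    total <- 0L
    for (idx in split(rows_s, chrom_rank(chrom[rows_s]))) {
      if (!is_autosome(chrom[idx[1]])) next
      runs <- status_runs(gnl$status[idx])
      total <- total + sum(runs$status != 0)
    }
    total
  })
  tibble(sample_id = names(out), N = as.integer(unlist(out)))
}

#' G2I classification thresholds
#'
#' The four cut-offs defining the three instability grades.  The defaults are
#' the published values: grade 1 requires a level of alteration A below 0.48
#' together with at most 42 altered regions; grade 3 requires A above 0.35
#' together with at least 65 altered regions; everything else is grade 2.
#'
#' @param a1,n1 Grade-1 cut-offs on A and N (defaults 0.48 and 42).
#' @param a2,n2 Grade-3 cut-offs on A and N (defaults 0.35 and 65).
#' @param boundary `"prose"` (default) uses strict inequalities on A and
#'   inclusive ones on N (grade 1: `A < a1 & N <= n1`; grade 3:
#'   `A > a2 & N >= n2`); `"strict"` makes all four inequalities strict.
#' @return An object of class `g2i_thresholds`.
#' @export
g2i_thresholds <- function(a1 = 0.48, n1 = 42L, a2 = 0.35, n2 = 65L,
                           boundary = c("prose", "strict")) {
  boundary <- match.arg(boundary)
  if (!(a1 >= 0 && a1 <= 1 && a2 >= 0 && a2 <= 1)) abort("a1 and a2 must lie in [0, 1]")
  n1 <- as.integer(n1)
  n2 <- as.integer(n2)
  if (any(is.na(c(n1, n2))) || n1 < 1L || n2 < 1L) abort("n1 and n2 must be positive integers")
  structure(
    list(a1 = a1, n1 = n1, a2 = a2, n2 = n2, boundary = boundary),
    class = "g2i_thresholds"
  )
}

#' @export
print.g2i_thresholds <- function(x, ...) {
  cat(sprintf(
    "G2I thresholds: grade 1 if A < %.3g & N %s %d; grade 3 if A > %.3g & N %s %d (%s boundary)\n",
    x$a1, if (x$boundary == "prose") "<=" else "<", x$n1,
    x$a2, if (x$boundary == "prose") ">=" else ">", x$n2, x$boundary
  ))
  invisible(x)
}

#' Classify samples into G2I grades
#'
#' Total, deterministic mapping of an (A, N) pair to grade 1, 2 or 3.  The
#' grade-1 rule is tested first, matching the index's definition; with the
#' published thresholds the two rules cannot both fire.
#'
#' @param A Numeric vector of alteration levels in [0, 1].
#' @param N Integer vector of altered-region counts.
#' @param thresholds A [g2i_thresholds()] object.
#' @return Integer vector of grades in {1, 2, 3}.
#' @export
#' @examples
#' classify_g2i(c(0.2, 0.5, 0.28), c(30, 100, 64))
classify_g2i <- function(A, N, thresholds = g2i_thresholds()) {
  stopifnot(inherits(thresholds, "g2i_thresholds"))
  if (any(!is.finite(A)) || any(!is.finite(N))) abort("A and N must be finite")
  if (thresholds$boundary == "prose") {
    g1 <- A < thresholds$a1 & N <= thresholds$n1
    g3 <- A > thresholds$a2 & N >= thresholds$n2
  } else {
    g1 <- A < thresholds$a1 & N < thresholds$n1
    g3 <- A > thresholds$a2 & N > thresholds$n2
  }
  ifelse(g1, 1L, ifelse(g3, 3L, 2L))
}

new_g2i_scores <- function(scores, thresholds) {
  structure(
    scores,
    thresholds = thresholds,
    class = c("g2i_scores", class(tibble()))
  )
}

#' Score GNL profiles with the G2I
#'
#' Local-score smoothing, then A, N and the grade per sample.
#'
#' @inheritParams fraction_genome_altered
#' @param thresholds A [g2i_thresholds()] object.
#' @param min_run Minimum run length for [smooth_gnl()] (default 2).
#' @return A `g2i_scores` tibble with `sample_id`, `A`, `N`, `grade`; the
#'   thresholds used are attached as an attribute and drive [autoplot()].
#' @export
score_gnl <- function(gnl, clone_map, thresholds = g2i_thresholds(), min_run = 2L) {
  smoothed <- smooth_gnl(gnl, clone_map, min_run = min_run)
  scores <- fraction_genome_altered(smoothed, clone_map) %>%
    left_join(count_altered_regions(smoothed, clone_map), by = "sample_id") %>%
    mutate(grade = classify_g2i(.data$A, .data$N, thresholds))
  new_g2i_scores(scores, thresholds)
}

#' Score log2 profiles end to end
#'
#' Full pipeline: segmentation and smoothing, residual-SD GNL calling,
#' local-score smoothing, then (A, N) and the grade.
#'
#' @inheritParams gnl_profiles
#' @inheritParams score_gnl
#' @return A `g2i_scores` tibble (see [score_gnl()]).
#' @export
score_profiles <- function(profiles, clone_map, thresholds = g2i_thresholds(),
                           penalty = NULL, min_seg_len = 2L, sd_multiplier = 1,
                           min_run = 2L) {
  gnl <- gnl_profiles(profiles, clone_map,
    penalty = penalty,
    min_seg_len = min_seg_len, sd_multiplier = sd_multiplier
  )
  score_gnl(gnl, clone_map, thresholds = thresholds, min_run = min_run)
}

# Deviance of the logistic model of a binary outcome on grade as a factor;
# the grade-saturated MLE has fitted probability = per-grade event rate, so
# the deviance has a closed form.
grade_model_deviance <- function(grade, outcome) {
  dev <- 0
  for (g in unique(grade)) {
    n_g <- sum(grade == g)
    y_g <- sum(outcome[grade == g])
    for (cnt in c(y_g, n_g - y_g)) {
      if (cnt > 0) dev <- dev - 2 * cnt * log(cnt / n_g)
    }
  }
  dev
}

#' Grid search for discriminating thresholds
#'
#' Exhaustive search over candidate (a1, n1, a2, n2) quadruples, scoring each
#' by the deviance of the logistic model of the outcome on the resulting
#' three-grade factor (lower is better).  Ties are broken toward fewer
#' grade-2 samples, then lexicographically on (a1, n1, a2, n2).  Overlapping
#' regions (a1 >= a2) are allowed, as in the published cut-offs.
#'
#' @param scores A tibble with `A` and `N` columns (e.g. from [score_gnl()]).
#' @param outcomes Binary outcome vector (0/1), one per row of `scores`.
#' @param a_grid,n_grid Candidate values for the A and N cut-offs; every
#'   combination of (a1, a2) from `a_grid` and (n1, n2) from `n_grid` is
#'   evaluated.
#' @param boundary Boundary convention, see [g2i_thresholds()].
#' @return The best [g2i_thresholds()], with the achieved deviance attached
#'   as attribute `deviance`.
#' @export
optimize_thresholds <- function(scores, outcomes, a_grid, n_grid,
                                boundary = c("prose", "strict")) {
  boundary <- match.arg(boundary)
  outcomes <- as.integer(outcomes)
  if (length(outcomes) != nrow(scores)) abort("outcomes must have one value per score row")
  if (length(unique(outcomes)) < 2) abort("outcomes must contain both classes")
  a_grid <- sort(unique(a_grid))
  n_grid <- sort(unique(as.integer(n_grid)))
  cand <- expand.grid(a1 = a_grid, n1 = n_grid, a2 = a_grid, n2 = n_grid)
  cand <- cand[order(cand$a1, cand$n1, cand$a2, cand$n2), ]
  best <- NULL
  any_nondegenerate <- FALSE
  for (i in seq_len(nrow(cand))) {
    th <- g2i_thresholds(cand$a1[i], cand$n1[i], cand$a2[i], cand$n2[i],
      boundary = boundary
    )
    grade <- classify_g2i(scores$A, scores$N, th)
    if (length(unique(grade)) < 2) next
    any_nondegenerate <- TRUE
    dev <- grade_model_deviance(grade, outcomes)
    n2cnt <- sum(grade == 2L)
    if (is.null(best) ||
      dev < best$dev - 1e-9 ||
      (abs(dev - best$dev) <= 1e-9 && n2cnt < best$n2cnt)) {
      best <- list(th = th, dev = dev, n2cnt = n2cnt)
    }
  }
  if (!any_nondegenerate) {
    abort("Degenerate grid: every candidate assigns all samples to one grade")
  }
  structure(best$th, deviance = best$dev)
}
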