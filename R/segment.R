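# Piecewise-constant smoothing of log2 ratios and gain/normal/loss calling.
#
# The segmenter is a penalized least-squares fit: over all tilings of a
# chromosome into segments of at least `min_seg_len` clones it minimizes
#   sum of squared deviations from segment means + penalty * (#segments),
# solved exactly by an O(n^2) dynamic program (optimal partitioning).  The
# smoothed value of a clone is its segment mean.  This is a documented
# substitute for GLAD-style smoothing: the downstream contract is only a
# deterministic piecewise-constant fit.

#' Segment one chromosome of log2 ratios
#'
#' Exact minimizer of `SSE + penalty * k` over tilings into segments of at
#' least `min_seg_len` clones (a chromosome shorter than `min_seg_len`
#' becomes a single segment).  With equal fit, fewer segments always win
#' because the penalty is kept strictly positive.
#'
#' @param y Numeric vector of log2 ratios for one chromosome, in genome
#'   order, without missing values.
#' @param penalty Non-negative penalty per segment; a zero penalty is lifted
#'   to a tiny positive floor so ties resolve toward fewer segments.
#' @param min_seg_len Minimum clones per segment (default 2).
#' @return A tibble with one row per segment: `start`, `end` (indices into
#'   `y`), `n_clones`, `mean`.
#' @export
#' @examples
#' segment_profile(c(rep(0, 10), rep(1, 10)), penalty = 0.5)
segment_profile <- function(y, penalty, min_seg_len = 2L) {
  if (!is.numeric(y) || anyNA(y)) abort("y must be a numeric vector without NA")
  if (!is.finite(penalty) || penalty < 0) abort("penalty must be finite and non-negative")
  min_seg_len <- as.integer(min_seg_len)
  if (is.na(min_seg_len) || min_seg_len < 1L) abort("min_seg_len must be >= 1")
  n <- length(y)
  if (n == 0L) {
    return(tibble(start = integer(), end = integer(), n_clones = integer(), mean = double()))
  }
  penalty <- max(penalty, 1e-9)
  cs1 <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  f <- rep(Inf, n + 1L)
  f[1L] <- 0
  back <- integer(n)
  for (j in seq_len(n)) {
    ts <- if (j - min_seg_len >= min_seg_len) {
      c(0L, seq.int(min_seg_len, j - min_seg_len))
    } else {
      0L
    }
    if (j < min_seg_len && j < n) {
      # prefix too short for a legal segment and not the whole chromosome
      ts <- integer(0)
    }
    if (length(ts) == 0L) next
    len <- j - ts
    s1 <- cs1[j + 1L] - cs1[ts + 1L]
    s2 <- cs2[j + 1L] - cs2[ts + 1L]
    cost <- f[ts + 1L] + (s2 - s1^2 / len) + penalty
    k <- which.min(cost)
    f[j + 1L] <- cost[k]
    back[j] <- ts[k]
  }
  starts <- integer(0)
  ends <- integer(0)
  j <- n
  while (j > 0L) {
    t <- back[j]
    starts <- c(t + 1L, starts)
    ends <- c(j, ends)
    j <- t
  }
  tibble(
    start = starts,
    end = ends,
    n_clones = ends - starts + 1L,
    mean = (cs1[ends + 1L] - cs1[starts]) / (ends - starts + 1L)
  )
}

# Robust per-sample noise estimate: MAD of within-chromosome first
# differences divided by sqrt(2).
noise_sigma <- function(log2, chromosome) {
  d <- unlist(lapply(split(log2, chrom_rank(chromosome)), function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2) diff(v) else numeric(0)
  }), use.names = FALSE)
  if (length(d) == 0) return(0)
  mad(d, center = 0) / sqrt(2)
}

#' Smooth log2 profiles by exact penalized segmentation
#'
#' Applies [segment_profile()] per sample and chromosome and attaches the
#' segment means as a `smoothed` column.  Missing clones are skipped (they
#' stay `NA`); segmentation runs on the observed clones of each chromosome.
#'
#' @param profiles Long tibble with `sample_id`, `clone_id`, `log2`.
#' @param clone_map Clone map the profiles are aligned to.
#' @param penalty Penalty per segment.  `NULL` (default) uses a BIC-like
#'   `2 * sigma^2 * log(n)` per chromosome, with `sigma` a per-sample robust
#'   noise estimate (MAD of successive differences / sqrt(2)) and `n` the
#'   chromosome's clone count.
#' @param min_seg_len Minimum clones per segment (default 2).
#' @return `profiles` with an added `smoothed` column.
#' @export
smooth_profiles <- function(profiles, clone_map, penalty = NULL, min_seg_len = 2L) {
  if (!is.null(penalty) && (!is.finite(penalty) || penalty < 0)) {
    abort("penalty must be NULL or a finite non-negative number")
  }
  chrom <- clone_map$chromosome[match(profiles$clone_id, clone_map$clone_id)]
  if (anyNA(chrom)) abort("profiles contain clone_ids absent from the clone map")
  profiles$smoothed <- NA_real_
  for (s in unique(profiles$sample_id)) {
    rows_s <- which(profiles$sample_id == s)
    y_all <- profiles$log2[rows_s]
    chr_s <- chrom[rows_s]
    sigma <- noise_sigma(y_all, chr_s)
    for (idx in split(seq_along(y_all), chrom_rank(chr_s))) {
      obs <- idx[!is.na(y_all[idx])]
      if (length(obs) == 0) next
      pen <- penalty %||% (2 * sigma^2 * log(length(idx)))
      segs <- segment_profile(y_all[obs], penalty = pen, min_seg_len = min_seg_len)
      sm <- rep(segs$mean, segs$n_clones)
      profiles$smoothed[rows_s[obs]] <- sm
    }
  }
  profiles
}

#' Residual standard deviation between normalized and smoothed ratios
#'
#' The per-sample noise scale used as the gain/loss threshold: the sample
#' standard deviation (n - 1 denominator) of `log2 - smoothed`, restricted
#' to autosomal clones.
#'
#' @param profiles Long tibble with `sample_id`, `clone_id`, `log2`,
#'   `smoothed` (see [smooth_profiles()]).
#' @param clone_map Clone map with chromosome labels.
#' @return A tibble with `sample_id`, `residual_sd`, `n_residuals`.
#' @export
residual_sd <- function(profiles, clone_map) {
  if (!"smoothed" %in% names(profiles)) abort("profiles must carry a smoothed column")
  chrom <- clone_map$chromosome[match(profiles$clone_id, clone_map$clone_id)]
  profiles %>%
    mutate(
      .auto = is_autosome(chrom),
      .res = .data$log2 - .data$smoothed
    ) %>%
    filter(.data$.auto, is.finite(.data$.res)) %>%
    group_by(.data$sample_id) %>%
    summarise(
      residual_sd = {
        if (dplyr::n() < 2) abort("Fewer than 2 usable autosomal residuals for a sample")
        sd(.data$.res)
      },
      n_residuals = dplyr::n(),
      .groups = "drop"
    )
}

#' Call gain/normal/loss states from smoothed ratios
#'
#' A clone is called a gain when its smoothed log2 ratio exceeds
#' `sd_multiplier * residual_sd` of its sample, a loss when it falls below
#' the negative threshold, and normal otherwise.  The inequalities are
#' strict: a value exactly at the threshold stays normal.
#'
#' @param profiles Long tibble with `sample_id`, `clone_id`, `smoothed`.
#' @param clone_map Clone map (used for the autosomal residual SD).
#' @param sd_multiplier Multiplier on the residual SD (default 1).
#' @param sds Optional precomputed tibble from [residual_sd()]; computed from
#'   `profiles` when `NULL`.
#' @return `profiles` with an added integer `status` column in {-1, 0, +1}
#'   (`NA` where `smoothed` is missing).
#' @export
call_gnl <- function(profiles, clone_map, sd_multiplier = 1, sds = NULL) {
  if (sd_multiplier < 0) abort("sd_multiplier must be non-negative")
  sds <- sds %||% residual_sd(profiles, clone_map)
  thr <- sd_multiplier * sds$residual_sd[match(profiles$sample_id, sds$sample_id)]
  if (anyNA(thr)) abort("Missing residual SD for some samples")
  degenerate <- sds$sample_id[sds$residual_sd == 0]
  if (length(degenerate) > 0 &&
    any(profiles$smoothed[profiles$sample_id %in% degenerate] != 0, na.rm = TRUE)) {
    warn(sprintf(
      "Residual SD is 0 for %d sample(s); every non-zero smoothed value becomes a call",
      length(degenerate)
    ))
  }
  profiles$status <- ifelse(profiles$smoothed > thr, 1L,
    ifelse(profiles$smoothed < -thr, -1L, 0L)
  )
  profiles$status <- as.integer(profiles$status)
  profiles
}

#' Full log2-to-GNL pipeline
#'
#' Convenience composition: [smooth_profiles()], [residual_sd()],
#' [call_gnl()].
#'
#' @inheritParams smooth_profiles
#' @inheritParams call_gnl
#' @return `profiles` with `smoothed` and `status` columns.
#' @export
gnl_profiles <- function(profiles, clone_map, penalty = NULL, min_seg_len = 2L,
                         sd_multiplier = 1) {
  profiles %>%
    smooth_profiles(clone_map, penalty = penalty, min_seg_len = min_seg_len) %>%
    call_gnl(clone_map, sd_multiplier = sd_multiplier)
}
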