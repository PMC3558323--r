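# Shared fixtures and independent oracles for the test suite.

# A small two-chromosome arm table: chr1 100 kb (centromere 40 kb),
# chr2 60 kb (centromere 30 kb), X 50 kb (centromere 20 kb).
tiny_arm_table <- function() {
  tibble::tibble(
    chromosome = c("1", "2", "X"),
    centromere_position = c(40e3, 30e3, 20e3),
    length = c(100e3, 60e3, 50e3),
    acrocentric = FALSE
  )
}

# Clone map on the tiny arm table: evenly spaced 1 kb clones.
# chr1: 10 clones (4 on p, 6 on q); chr2: 6 (3p/3q); X: 4 (2p/2q).
tiny_clone_map <- function() {
  starts <- list(
    "1" = seq(5e3, 95e3, length.out = 10),
    "2" = seq(5e3, 55e3, length.out = 6),
    "X" = seq(5e3, 45e3, length.out = 4)
  )
  map <- dplyr::bind_rows(lapply(names(starts), function(ch) {
    tibble::tibble(
      clone_id = sprintf("c%s_%02d", ch, seq_along(starts[[ch]])),
      chromosome = ch,
      start = round(starts[[ch]]),
      end = round(starts[[ch]]) + 999
    )
  }))
  assign_arms(map, tiny_arm_table())
}

# Long profile tibble from a named list of per-clone value vectors.
profiles_tbl <- function(values_by_sample, clone_map, value = "log2") {
  dplyr::bind_rows(lapply(names(values_by_sample), function(s) {
    out <- tibble::tibble(
      sample_id = s,
      clone_id = clone_map$clone_id
    )
    out[[value]] <- values_by_sample[[s]]
    out
  }))
}

gnl_tbl <- function(status_by_sample, clone_map) {
  dplyr::bind_rows(lapply(names(status_by_sample), function(s) {
    tibble::tibble(
      sample_id = s,
      clone_id = clone_map$clone_id,
      status = as.integer(status_by_sample[[s]])
    )
  }))
}

# Adjusted Rand index between two labelings (direct pair-counting formula).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Independent segmentation oracle: enumerates every breakpoint set honoring
# the minimum segment length (recursively, without dynamic programming) and
# returns the minimum of SSE + penalty * k.
exhaustive_segment_cost <- function(y, penalty, min_seg_len = 2L) {
  n <- length(y)
  sse <- function(i, j) {
    v <- y[i:j]
    sum((v - mean(v))^2)
  }
  best <- Inf
  recurse <- function(start, cost_so_far) {
    # segment from `start` to some end e, then recurse
    for (e in seq(min(start + min_seg_len - 1L, n), n)) {
      if (e - start + 1L < min_seg_len && e < n) next
      c2 <- cost_so_far + sse(start, e) + penalty
      if (e == n) {
        if (c2 < best) best <<- c2
      } else if (n - e >= min_seg_len) {
        recurse(e + 1L, c2)
      }
    }
  }
  recurse(1L, 0)
  best
}

# Direct two-sided Fisher p for a 2x2 table by hypergeometric summation.
fisher_p_oracle <- function(k1, n1, k2, n2) {
  k <- k1 + k2
  support <- max(0, k - n2):min(n1, k)
  probs <- stats::dhyper(support, n1, n2, k)
  p_obs <- stats::dhyper(k1, n1, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-square statistic by direct formula (used by the MC oracle).
chisq_stat <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

default_archetypes <- c(
  "flat_a", "t1q16q_b", "c1q7_c", "chr8_16_d", "complex_e", "firestorm_f"
)

# Archetype spec stripped of random background (focal events, amplicons,
# optional arm events) so planted runs are exactly the deterministic arms.
bare_archetype <- function(name, noise_sd = 0.1) {
  spec <- archetype_spec(name, noise_sd = noise_sd)
  spec$focal_lambda <- 0
  spec$amplicon_lambda <- 0
  spec$optional_arm_events <- NULL
  spec
}
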