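# Internal helpers shared across modules: chromosome ordering and the
# run-length machinery used by local-score smoothing, region counting and
# amplicon calling.

CHROMOSOMES <- c(as.character(1:22), "X", "Y")
AUTOSOMES <- as.character(1:22)

# Number of consecutive missing clones that breaks run adjacency.  Runs of
# altered clones are bridged across shorter dropouts so that array dropouts
# do not manufacture spurious breakpoints.
GAP_BREAK <- 5L

chrom_rank <- function(chromosome) {
  match(as.character(chromosome), CHROMOSOMES)
}

is_autosome <- function(chromosome) {
  as.character(chromosome) %in% AUTOSOMES
}

check_chromosomes <- function(chromosome, context = "input") {
  bad <- setdiff(unique(as.character(chromosome)), CHROMOSOMES)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown chromosome label(s) in %s: %s (expected 1-22, X, Y)",
      context, paste(bad, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Split clones of one chromosome into adjacency blocks
#'
#' Clones with missing values are dropped; a stretch of `GAP_BREAK` or more
#' consecutive missing clones breaks adjacency between its neighbours.
#' Returns an integer block id per clone (NA for missing clones).
#' @noRd
gap_blocks <- function(missing) {
  n <- length(missing)
  block <- rep(NA_integer_, n)
  cur <- 1L
  gap <- 0L
  seen_any <- FALSE
  for (i in seq_len(n)) {
    if (missing[i]) {
      gap <- gap + 1L
    } else {
      if (seen_any && gap >= GAP_BREAK) cur <- cur + 1L
      block[i] <- cur
      gap <- 0L
      seen_any <- TRUE
    }
  }
  block
}

#' Maximal equal-status runs within adjacency blocks of one chromosome
#'
#' @param status integer vector (may contain NA = missing clone)
#' @return tibble with one row per run: block, status, start, end, length
#'   (indices into the original vector; length counts non-missing clones)
#' @noRd
status_runs <- function(status) {
  block <- gap_blocks(is.na(status))
  keep <- which(!is.na(block))
  if (length(keep) == 0) {
    return(tibble(
      block = integer(), status = integer(),
      start = integer(), end = integer(), length = integer()
    ))
  }
  st <- status[keep]
  bl <- block[keep]
  new_run <- c(TRUE, st[-1] != st[-length(st)] | bl[-1] != bl[-length(bl)])
  run_id <- cumsum(new_run)
  starts <- keep[new_run]
  ends <- keep[c(new_run[-1], TRUE)]
  tibble(
    block = bl[new_run],
    status = st[new_run],
    start = starts,
    end = ends,
    length = as.integer(tabulate(run_id))
  )
}

# Cumulative-sum segment cost: sum of squared deviations from the segment mean.
seg_sse <- function(cs1, cs2, i, j) {
  n <- j - i + 1
  s1 <- cs1[j + 1] - cs1[i]
  s2 <- cs2[j + 1] - cs2[i]
  s2 - s1^2 / n
}

`%||%` <- function(x, y) if (is.null(x)) y else x
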