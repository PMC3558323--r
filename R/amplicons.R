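# Amplicon detection: focal high-level copy-number increases.
#
# An amplicon is a maximal run of at least `min_clones` contiguous clones
# whose inferred copy number exceeds `cn_threshold`.  Copy number is
# inferred from the smoothed (segment-mean) log2 ratio assuming a diploid
# reference and full tumor cellularity: CN = ploidy * 2^smoothed, so the
# default rule CN > 3 corresponds to smoothed > log2(3/2) ~ 0.585.

#' Call amplicons from smoothed profiles
#'
#' @param profiles Long tibble with `sample_id`, `clone_id`, `smoothed`
#'   (see [smooth_profiles()]).
#' @param clone_map Clone map the profiles are aligned to.
#' @param cn_threshold Copy-number cut-off (default 3, strict inequality).
#' @param min_clones Minimum contiguous clones (default 2).
#' @param ploidy Assumed reference ploidy (default 2, must be positive).
#' @return A tibble of calls: `sample_id`, `chromosome`, `first_clone`,
#'   `last_clone`, `n_clones`, `max_smoothed`, `max_copy_number`.  Runs are
#'   maximal and never overlap within a sample; a missing smoothed value
#'   breaks contiguity.
#' @export
call_amplicons <- function(profiles, clone_map, cn_threshold = 3,
                           min_clones = 2L, ploidy = 2) {
  if (ploidy <= 0) abort("ploidy must be positive")
  if (!"smoothed" %in% names(profiles)) abort("profiles must carry a smoothed column")
  min_clones <- as.integer(min_clones)
  out <- list()
  for (s in unique(profiles$sample_id)) {
    sub <- profiles[profiles$sample_id == s, ]
    sm <- sub$smoothed[match(clone_map$clone_id, sub$clone_id)]
    cn <- ploidy * 2^sm
    pass <- !is.na(cn) & cn > cn_threshold
    runs <- clone_runs(pass, clone_map)
    runs <- runs[runs$n_clones >= min_clones, , drop = FALSE]
    if (nrow(runs) > 0) {
      runs$sample_id <- s
      runs$max_smoothed <- vapply(seq_len(nrow(runs)), function(i) {
        max(sm[runs$first_index[i]:runs$last_index[i]], na.rm = TRUE)
      }, numeric(1))
      runs$max_copy_number <- ploidy * 2^runs$max_smoothed
      out[[s]] <- runs
    }
  }
  if (length(out) == 0) {
    empty <- clone_runs(logical(nrow(clone_map)), clone_map)
    empty$sample_id <- character(0)
    empty$max_smoothed <- numeric(0)
    empty$max_copy_number <- numeric(0)
    return(empty[, c(
      "sample_id", "chromosome", "first_clone", "last_clone",
      "first_index", "last_index", "n_clones", "max_smoothed", "max_copy_number"
    )])
  }
  bind_rows(out) %>%
    select(
      "sample_id", "chromosome", "first_clone", "last_clone",
      "first_index", "last_index", "n_clones", "max_smoothed", "max_copy_number"
    )
}

#' Summarize amplicon calls per group
#'
#' Reports, per group (and overall), the number of tumors with at least one
#' amplicon, the total number of amplicons, the mean per tumor and the mean
#' per amplicon-bearing tumor, plus recurrent amplicon regions obtained by
#' merging overlapping calls across samples.
#'
#' @param calls Call tibble from [call_amplicons()].
#' @param samples Character vector of all sample ids in the cohort
#'   (amplicon-free tumors enter the denominators).
#' @param groups Optional named vector mapping sample_id to a group label.
#' @return A list with `summary` (one row per group plus `"all"`) and
#'   `recurrent` (merged regions with the number of affected samples).
#' @export
amplicon_summary <- function(calls, samples, groups = NULL) {
  samples <- unique(as.character(samples))
  grp <- if (is.null(groups)) {
    setNames(rep("all", length(samples)), samples)
  } else {
    setNames(as.character(groups[samples]), samples)
  }
  per_sample <- tibble(sample_id = samples) %>%
    left_join(dplyr::count(calls, .data$sample_id, name = "n_amplicons"),
      by = "sample_id"
    ) %>%
    mutate(
      n_amplicons = ifelse(is.na(.data$n_amplicons), 0L, .data$n_amplicons),
      group = grp[.data$sample_id]
    )
  summarize_grp <- function(df, label) {
    tibble(
      group = label,
      n_tumors = nrow(df),
      tumors_with_amplicons = sum(df$n_amplicons > 0),
      amplicons = sum(df$n_amplicons),
      mean_per_tumor = ifelse(nrow(df) > 0, sum(df$n_amplicons) / nrow(df), 0),
      mean_per_bearing_tumor = ifelse(any(df$n_amplicons > 0),
        sum(df$n_amplicons) / sum(df$n_amplicons > 0), 0
      )
    )
  }
  summary <- if (is.null(groups)) {
    summarize_grp(per_sample, "all")
  } else {
    pieces <- lapply(split(per_sample, per_sample$group), function(df) {
      summarize_grp(df, df$group[1])
    })
    bind_rows(c(pieces, list(summarize_grp(per_sample, "all"))))
  }
  # merge overlapping calls (clone-index overlap) into recurrent regions
  recurrent <- tibble(
    chromosome = character(), first_index = integer(),
    last_index = integer(), n_samples = integer()
  )
  if (nrow(calls) > 0) {
    merged <- calls %>%
      arrange(chrom_rank(.data$chromosome), .data$first_index) %>%
      group_by(.data$chromosome) %>%
      mutate(
        new_region = cumsum(
          c(TRUE, .data$first_index[-1] > cummax(.data$last_index)[-dplyr::n()])
        )
      ) %>%
      group_by(.data$chromosome, .data$new_region) %>%
      summarise(
        first_index = min(.data$first_index),
        last_index = max(.data$last_index),
        n_samples = dplyr::n_distinct(.data$sample_id),
        .groups = "drop"
      ) %>%
      select(-"new_region")
    recurrent <- merged %>% arrange(chrom_rank(.data$chromosome), .data$first_index)
  }
  list(summary = summary, recurrent = recurrent)
}
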