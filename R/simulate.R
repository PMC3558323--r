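# Synthetic aCGH cohort generator.
#
# Cohorts are mixtures of six genomic archetypes mirroring the recurrent
# patterns of breast-tumor BAC-array profiles:
#   flat_a      flat profile, no planted events
#   t1q16q_b    1q gain + 16q loss (the t(1;16) pattern)
#   c1q7_c      1q gain + whole-chromosome-7 gain
#   chr8_16_d   8p-/8q+ and 16p+/16q- arm swaps
#   complex_e   many whole-arm gains/losses plus scattered focal events
#   firestorm_f few arm events but a storm of focal rearrangements and
#               frequent amplicons
# Planted segment means are -0.5 (one-copy loss), +0.4 (one-copy gain) and
# +1.0 (amplicon, copy number 4) on the log2 scale, with i.i.d. Gaussian
# probe noise (default sd 0.1) on top; background focal-event counts are
# Poisson with archetype-specific means chosen to land the altered-region
# count N in the ranges observed on real cohorts (tens of regions for the
# arm-driven archetypes, around ninety for the firestorm pattern).

SEGMENT_LEVELS <- c(loss = -0.5, gain = 0.4, amplicon = 1.0)

ARCHETYPES <- c("flat_a", "t1q16q_b", "c1q7_c", "chr8_16_d", "complex_e", "firestorm_f")

arm_ev <- function(chromosome, arm, direction) {
  tibble(chromosome = chromosome, arm = arm, direction = as.integer(direction))
}

#' Archetype specification
#'
#' Returns the event recipe of one genomic archetype: deterministic
#' whole-arm events, optional secondary arm events with their probability,
#' the background focal-event distribution (Poisson count, uniform length
#' range in clones, gain probability) and the amplicon count distribution.
#'
#' @param name One of `"flat_a"`, `"t1q16q_b"`, `"c1q7_c"`, `"chr8_16_d"`,
#'   `"complex_e"`, `"firestorm_f"`.
#' @param noise_sd Gaussian probe noise, log2 units (>= 0; default 0.1).
#' @param levels Named numeric vector of planted segment means
#'   (`loss`, `gain`, `amplicon`).
#' @return A list of class `g2i_archetype`.
#' @export
archetype_spec <- function(name = ARCHETYPES, noise_sd = 0.1,
                           levels = SEGMENT_LEVELS) {
  name <- match.arg(name)
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  stopifnot(all(c("loss", "gain", "amplicon") %in% names(levels)))
  base <- list(
    name = name, noise_sd = noise_sd, levels = levels,
    arm_events = arm_ev(character(), character(), integer()),
    optional_arm_events = NULL,
    focal_lambda = 0, focal_len = c(3L, 12L), focal_p_gain = 0.5,
    amplicon_lambda = 0, amplicon_len = c(2L, 4L)
  )
  spec <- switch(name,
    flat_a = base,
    t1q16q_b = within_list(base,
      arm_events = arm_ev(c("1", "16"), c("q", "q"), c(1L, -1L)),
      optional_arm_events = cbind(
        arm_ev(c("8", "11"), c("p", "q"), c(-1L, -1L)),
        prob = c(0.5, 0.5)
      ),
      focal_lambda = 45, amplicon_lambda = 1
    ),
    c1q7_c = within_list(base,
      arm_events = arm_ev(c("1", "7", "7"), c("q", "p", "q"), c(1L, 1L, 1L)),
      optional_arm_events = cbind(arm_ev("8", "q", 1L), prob = 0.5),
      focal_lambda = 45, amplicon_lambda = 2
    ),
    chr8_16_d = within_list(base,
      arm_events = arm_ev(
        c("8", "8", "16", "16"), c("p", "q", "p", "q"), c(-1L, 1L, 1L, -1L)
      ),
      optional_arm_events = cbind(
        arm_ev(c("6", "13", "17"), c("q", "q", "p"), c(-1L, -1L, -1L)),
        prob = c(0.5, 0.5, 0.5)
      ),
      focal_lambda = 45, amplicon_lambda = 2
    ),
    complex_e = within_list(base,
      arm_events = arm_ev(
        c("1", "1", "5", "5", "6", "8", "11", "12", "16", "16", "17", "20"),
        c("p", "q", "p", "q", "q", "q", "q", "q", "p", "q", "q", "q"),
        c(-1L, 1L, 1L, 1L, -1L, 1L, -1L, 1L, 1L, -1L, 1L, 1L)
      ),
      focal_lambda = 50, amplicon_lambda = 2
    ),
    firestorm_f = within_list(base,
      arm_events = arm_ev(c("16", "20"), c("p", "q"), c(1L, 1L)),
      focal_lambda = 85, focal_len = c(15L, 45L), focal_p_gain = 0.4,
      amplicon_lambda = 5
    )
  )
  structure(spec, class = "g2i_archetype")
}

within_list <- function(x, ...) {
  mods <- list(...)
  x[names(mods)] <- mods
  x
}

#' Simulate a BAC clone map
#'
#' Clones are allocated to chromosome arms proportionally to arm length
#' (at least one per arm) and placed on an even grid with uniform jitter,
#' so the median inter-clone spacing is close to genome length / n_clones
#' (about 0.5 Mb for the default 5878-clone array).  Acrocentric p arms
#' carry no clones.
#'
#' @param n_clones Number of clones (default 5878); must be at least twice
#'   the number of arms carrying clones.
#' @param arm_table Arm table (default [human_arm_table()]).
#' @param seed Optional integer seed for reproducibility.
#' @param clone_length Clone span in bp (default 150 kb).
#' @return A clone map tibble with `clone_id`, `chromosome`, `start`,
#'   `end`, `arm`.
#' @export
simulate_clone_map <- function(n_clones = 5878L, arm_table = human_arm_table(),
                               seed = NULL, clone_length = 150000) {
  validate_arm_table(arm_table)
  if (!is.null(seed)) withr::local_seed(seed)
  acro <- if ("acrocentric" %in% names(arm_table)) arm_table$acrocentric else FALSE
  arms <- bind_rows(
    tibble(
      chromosome = arm_table$chromosome[!acro], arm = "p",
      lo = 1, hi = arm_table$centromere_position[!acro]
    ),
    tibble(
      chromosome = arm_table$chromosome, arm = "q",
      lo = arm_table$centromere_position + 1, hi = arm_table$length
    )
  )
  arms$len <- arms$hi - arms$lo + 1
  n_arms <- nrow(arms)
  if (n_clones < 2L * n_arms) {
    abort(sprintf("n_clones must be at least %d (2 per arm)", 2L * n_arms))
  }
  raw <- n_clones * arms$len / sum(arms$len)
  alloc <- pmax(1L, floor(raw))
  while (sum(alloc) < n_clones) {
    i <- which.max(raw - alloc)
    alloc[i] <- alloc[i] + 1L
  }
  while (sum(alloc) > n_clones) {
    ok <- alloc > 1L
    i <- which(ok)[which.min((raw - alloc)[ok])]
    alloc[i] <- alloc[i] - 1L
  }
  pieces <- lapply(seq_len(n_arms), function(i) {
    k <- alloc[i]
    spacing <- arms$len[i] / k
    centre <- arms$lo[i] + (seq_len(k) - 0.5) * spacing +
      runif(k, -0.35, 0.35) * spacing
    start <- pmax(arms$lo[i], round(centre - clone_length / 2))
    tibble(
      chromosome = arms$chromosome[i],
      start = start,
      end = start + clone_length - 1
    )
  })
  map <- bind_rows(pieces) %>%
    arrange(chrom_rank(.data$chromosome), .data$start) %>%
    group_by(.data$chromosome) %>%
    mutate(clone_id = sprintf("chr%s_%04d", .data$chromosome, row_number())) %>%
    ungroup() %>%
    select("clone_id", "chromosome", "start", "end")
  assign_arms(map, arm_table)
}

# Fast planted A/N from a status vector (autosomes only), mirroring the
# scoring definitions without tibble overhead.
planted_a_n <- function(status, chromosome, arm) {
  auto <- is_autosome(chromosome)
  key <- paste0(chromosome[auto], arm[auto])
  props <- tapply(status[auto] != 0, key, mean)
  a <- mean(props)
  n <- 0L
  for (idx in split(which(auto), chromosome[auto])) {
    r <- rle(status[idx])
    n <- n + sum(r$values != 0)
  }
  list(A = unname(a), N = as.integer(n))
}

# Plant the event structure of one archetype on a clone map.  Returns the
# per-clone planted level and status plus the truth record.
plant_profile <- function(spec, clone_map, thresholds = g2i_thresholds()) {
  n <- nrow(clone_map)
  chrom <- clone_map$chromosome
  arm <- clone_map$arm
  status <- integer(n)
  amp <- logical(n)
  ev <- spec$arm_events
  if (!is.null(spec$optional_arm_events) && nrow(spec$optional_arm_events) > 0) {
    keep <- runif(nrow(spec$optional_arm_events)) < spec$optional_arm_events$prob
    ev <- bind_rows(ev, spec$optional_arm_events[keep, c("chromosome", "arm", "direction")])
  }
  for (i in seq_len(nrow(ev))) {
    idx <- which(chrom == ev$chromosome[i] & arm == ev$arm[i])
    status[idx] <- ev$direction[i]
  }
  chrom_first <- tapply(seq_len(n), chrom, min)[chrom]
  chrom_last <- tapply(seq_len(n), chrom, max)[chrom]
  place_events <- function(count, len_range, dirs, is_amp) {
    placed <- 0L
    auto_idx <- which(is_autosome(chrom))
    for (e in seq_len(count)) {
      len <- sample(len_range[1]:len_range[2], 1L)
      dir <- dirs[e]
      for (try in seq_len(100L)) {
        i0 <- sample(auto_idx, 1L)
        i1 <- i0 + len - 1L
        if (i1 > n || chrom[i1] != chrom[i0]) next
        # an event may touch a chromosome end but must not strand a single
        # normal clone there (unresolvable for the 2-clone-minimum smoother)
        if (i0 - chrom_first[i0] == 1L || chrom_last[i1] - i1 == 1L) next
        w0 <- max(1L, i0 - 2L)
        w1 <- min(n, i1 + 2L)
        window <- w0:w1
        window <- window[chrom[window] == chrom[i0]]
        if (any(status[window] != 0L)) next
        status[i0:i1] <<- dir
        if (is_amp) amp[i0:i1] <<- TRUE
        placed <- placed + 1L
        break
      }
    }
    placed
  }
  n_focal <- rpois(1L, spec$focal_lambda)
  focal_dirs <- ifelse(runif(n_focal) < spec$focal_p_gain, 1L, -1L)
  n_focal_placed <- place_events(n_focal, spec$focal_len, focal_dirs, FALSE)
  n_amp <- rpois(1L, spec$amplicon_lambda)
  n_amp_placed <- place_events(n_amp, spec$amplicon_len, rep(1L, n_amp), TRUE)
  level <- numeric(n)
  level[status == -1L] <- spec$levels[["loss"]]
  level[status == 1L] <- spec$levels[["gain"]]
  level[amp] <- spec$levels[["amplicon"]]
  an <- planted_a_n(status, chrom, arm)
  truth <- list(
    archetype = spec$name,
    status = status,
    level = level,
    amplicon = amp,
    A = an$A,
    N = an$N,
    grade = classify_g2i(an$A, an$N, thresholds),
    n_focal = n_focal_placed,
    n_amplicons = n_amp_placed
  )
  truth
}

#' Simulate one aCGH profile
#'
#' Plants the archetype's whole-arm events, background focal events and
#' amplicons on the clone map (events never overlap and are separated by at
#' least two normal clones), then adds Gaussian probe noise.
#'
#' @param archetype An archetype name or [archetype_spec()] object.
#' @param clone_map Clone map from [simulate_clone_map()].
#' @param seed Optional integer seed.
#' @param noise_sd Overrides the spec's probe noise when not `NULL`.
#' @param thresholds Thresholds used to record the planted grade.
#' @return A list with `log2` (tibble `clone_id`, `log2`) and `truth`
#'   (planted per-clone status and level, amplicon flags, the planted
#'   A, N and grade, and placed event counts).
#' @export
simulate_profile <- function(archetype, clone_map, seed = NULL, noise_sd = NULL,
                             thresholds = g2i_thresholds()) {
  spec <- if (inherits(archetype, "g2i_archetype")) archetype else archetype_spec(archetype)
  if (!is.null(noise_sd)) spec$noise_sd <- noise_sd
  if (spec$noise_sd < 0) abort("noise_sd must be >= 0")
  if (!is.null(seed)) withr::local_seed(seed)
  truth <- plant_profile(spec, clone_map, thresholds)
  log2v <- truth$level + rnorm(nrow(clone_map), 0, spec$noise_sd)
  list(
    log2 = tibble(clone_id = clone_map$clone_id, log2 = log2v),
    truth = truth
  )
}

#' Cohort simulation configuration
#'
#' @param n_samples Number of tumors to simulate.
#' @param n_clones Clones on the simulated array (default 5878).
#' @param weights Named archetype mixture weights (default: the archetype
#'   group sizes of a 135-tumor cohort, 34/25/16/13/35/12); normalized to
#'   sum to 1.
#' @param relapse_probs Relapse probability per planted grade (defaults
#'   1/19, 23/88, 21/28 for grades 1, 2, 3).
#' @param noise_sd Gaussian probe noise (default 0.1).
#' @param arm_table Arm table (default [human_arm_table()]).
#' @param thresholds Thresholds used for the planted grade.
#' @param seed Optional integer seed.
#' @return A list of class `g2i_sim_config`.
#' @export
simulation_config <- function(n_samples,
                              n_clones = 5878L,
                              weights = c(
                                flat_a = 34, t1q16q_b = 25, c1q7_c = 16,
                                chr8_16_d = 13, complex_e = 35, firestorm_f = 12
                              ) / 135,
                              relapse_probs = c(1 / 19, 23 / 88, 21 / 28),
                              noise_sd = 0.1,
                              arm_table = human_arm_table(),
                              thresholds = g2i_thresholds(),
                              seed = NULL) {
  if (!all(names(weights) %in% ARCHETYPES)) abort("Unknown archetype in weights")
  if (any(weights < 0) || sum(weights) <= 0) abort("weights must be non-negative and sum > 0")
  weights <- weights / sum(weights)
  if (length(relapse_probs) != 3 || any(relapse_probs < 0 | relapse_probs > 1)) {
    abort("relapse_probs must be three probabilities in [0, 1]")
  }
  structure(
    list(
      n_samples = as.integer(n_samples), n_clones = as.integer(n_clones),
      weights = weights, relapse_probs = relapse_probs, noise_sd = noise_sd,
      arm_table = arm_table, thresholds = thresholds, seed = seed
    ),
    class = "g2i_sim_config"
  )
}

# Grade-conditional clinical category probabilities, mirroring the
# cross-tabulations of a 135-tumor reference cohort (columns grade 1/2/3).
CLINICAL_PROBS <- list(
  node_pN0 = c(12 / 19, 43 / 88, 20 / 28),
  age_le55 = c(8 / 19, 51 / 88, 11 / 28),
  size_le20 = c(16 / 19, 57 / 88, 17 / 28),
  sbr = cbind(c(6, 12, 1) / 19, c(15, 48, 25) / 88, c(4, 11, 13) / 28),
  hr_pos = c(18 / 19, 74 / 88, 24 / 28),
  npi = cbind(c(6, 13, 0) / 19, c(20, 50, 18) / 88, c(4, 22, 2) / 28),
  mib1_hi = c(1 / 19, 28 / 88, 13 / 28),
  tp53 = c(0, 24 / 88, 15 / 28),
  intrinsic = cbind(
    c(16, 2, 1, 0, 0) / 19, c(55, 19, 6, 6, 2) / 88, c(12, 12, 3, 1, 0) / 28
  )
)

#' Simulate an aCGH cohort with clinical outcomes
#'
#' Draws archetypes from the mixture, plants each profile, computes the
#' planted grade from the truth tiling, and draws relapse
#' Bernoulli(p[grade]) with follow-up uniform on (6, 120) months for
#' relapsers and censoring beyond 131 months otherwise.  The remaining
#' clinical covariates are drawn with grade-conditional category
#' frequencies matching a 135-tumor reference cohort.
#'
#' @param config A [simulation_config()] object.
#' @param keep_profiles Keep the per-clone log2 values (default TRUE; set
#'   FALSE for truth-level studies where only grades and outcomes matter).
#' @return A list with `clone_map`, `profiles` (long tibble `sample_id`,
#'   `clone_id`, `log2`, or `NULL`), `clinical`, `truth` (per-sample tibble
#'   with archetype and planted A/N/grade) and `truth_details` (list of
#'   per-sample planted structures).
#' @export
simulate_cohort <- function(config, keep_profiles = TRUE) {
  stopifnot(inherits(config, "g2i_sim_config"))
  if (!is.null(config$seed)) withr::local_seed(config$seed)
  clone_map <- simulate_clone_map(config$n_clones, config$arm_table)
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  archetypes <- sample(names(config$weights), n, replace = TRUE, prob = config$weights)
  specs <- lapply(
    setNames(nm = unique(archetypes)), archetype_spec,
    noise_sd = config$noise_sd
  )
  truths <- vector("list", n)
  values <- if (keep_profiles) matrix(NA_real_, nrow(clone_map), n) else NULL
  for (i in seq_len(n)) {
    truth <- plant_profile(specs[[archetypes[i]]], clone_map, config$thresholds)
    truths[[i]] <- truth
    if (keep_profiles) {
      values[, i] <- truth$level + rnorm(nrow(clone_map), 0, config$noise_sd)
    }
  }
  grade <- vapply(truths, `[[`, integer(1), "grade")
  relapse <- rbinom(n, 1L, config$relapse_probs[grade])
  follow_up <- ifelse(relapse == 1L, runif(n, 6, 120), 131 + runif(n, 1, 60))
  draw_cat <- function(p_by_grade, yes, no) {
    ifelse(runif(n) < p_by_grade[grade], yes, no)
  }
  draw_multi <- function(mat, labels) {
    vapply(seq_len(n), function(i) {
      sample(labels, 1L, prob = mat[, grade[i]])
    }, character(1))
  }
  size_small <- runif(n) < CLINICAL_PROBS$size_le20[grade]
  npi_row <- draw_multi(CLINICAL_PROBS$npi, c("1+2", "3", "4"))
  clinical <- tibble(
    sample_id = ids,
    relapse = relapse,
    follow_up = round(follow_up, 1),
    node_status = draw_cat(CLINICAL_PROBS$node_pN0, "pN0", "pN+"),
    age_group = draw_cat(CLINICAL_PROBS$age_le55, "<=55", ">55"),
    size_mm = round(ifelse(size_small, runif(n, 8, 20), runif(n, 21, 50)), 1),
    sbr_grade = draw_multi(CLINICAL_PROBS$sbr, c("1", "2", "3")),
    hr_status = draw_cat(CLINICAL_PROBS$hr_pos, "+", "-"),
    npi_class = ifelse(npi_row == "1+2", sample(c("1", "2"), n, replace = TRUE), npi_row),
    mib1 = draw_cat(CLINICAL_PROBS$mib1_hi, ">=20%", "<20%"),
    tp53_altered = as.integer(runif(n) < CLINICAL_PROBS$tp53[grade]),
    intrinsic_class = draw_multi(
      CLINICAL_PROBS$intrinsic, c("LA", "LB", "HER2", "Basal", "unclassified")
    )
  )
  profiles <- NULL
  if (keep_profiles) {
    profiles <- tibble(
      sample_id = rep(ids, each = nrow(clone_map)),
      clone_id = rep(clone_map$clone_id, n),
      log2 = as.vector(values)
    )
  }
  truth_tbl <- tibble(
    sample_id = ids,
    archetype = archetypes,
    A = vapply(truths, `[[`, numeric(1), "A"),
    N = vapply(truths, `[[`, integer(1), "N"),
    grade = grade,
    n_focal = vapply(truths, `[[`, integer(1), "n_focal"),
    n_amplicons = vapply(truths, `[[`, integer(1), "n_amplicons")
  )
  names(truths) <- ids
  list(
    clone_map = clone_map, profiles = profiles, clinical = clinical,
    truth = truth_tbl, truth_details = truths
  )
}

#' Simulate a log2 expression matrix with planted group differences
#'
#' Signal probes differ between the two groups by `effect` log2 units.  By
#' default the signature is bidirectional, as real ones are: the first half
#' of the signal probes is up in the focal group and down in the rest, the
#' second half the reverse (each group shifted by `effect / 2`), so the
#' signature carries correlated structure in both groups.  With
#' `bidirectional = FALSE` the focal group is simply shifted up by `effect`.
#'
#' @param n_probes Number of probes.
#' @param labels Logical vector over samples; `TRUE` marks the focal group.
#' @param n_signal Number of differentially expressed probes.
#' @param effect Between-group difference (log2 units) on the signal probes.
#' @param sd Within-group standard deviation (default 1).
#' @param bidirectional Split the signature into up- and down-regulated
#'   halves (default TRUE).
#' @param seed Optional integer seed.
#' @return A list with `expr` (probes x samples matrix) and
#'   `signal_probes`.
#' @export
simulate_expression <- function(n_probes, labels, n_signal = 0L, effect = 0,
                                sd = 1, bidirectional = TRUE, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  n_samples <- length(labels)
  ids <- names(labels) %||% sprintf("S%04d", seq_len(n_samples))
  expr <- matrix(rnorm(n_probes * n_samples, 0, sd),
    nrow = n_probes,
    dimnames = list(sprintf("probe_%05d", seq_len(n_probes)), ids)
  )
  signal <- character(0)
  if (n_signal > 0) {
    signal <- rownames(expr)[seq_len(n_signal)]
    if (bidirectional) {
      up <- seq_len(ceiling(n_signal / 2))
      down <- setdiff(seq_len(n_signal), up)
      expr[up, labels] <- expr[up, labels] + effect / 2
      expr[up, !labels] <- expr[up, !labels] - effect / 2
      if (length(down) > 0) {
        expr[down, labels] <- expr[down, labels] - effect / 2
        expr[down, !labels] <- expr[down, !labels] + effect / 2
      }
    } else {
      expr[seq_len(n_signal), labels] <- expr[seq_len(n_signal), labels] + effect
    }
  }
  list(expr = expr, signal_probes = signal)
}
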