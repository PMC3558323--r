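# ggplot2 views of the main result types: the (A, N) instability plane,
# genomic profiles with their smoothed fit, group frequency plots, and an
# MDS view of profile clusters.

#' Plot G2I scores in the (A, N) plane
#'
#' Scatter plot of the cohort on the two index parameters with the
#' classification thresholds as dashed lines — the standard view of the
#' three instability grades.
#'
#' @param object A `g2i_scores` tibble from [score_gnl()]/[score_profiles()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.g2i_scores <- function(object, ...) {
  th <- attr(object, "thresholds")
  df <- as_tibble(object)
  df$grade <- factor(df$grade, levels = c(1, 2, 3), labels = paste0("G2I-", 1:3))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$N, y = .data$A, colour = .data$grade
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "Number of altered regions (N)",
      y = "Overall level of genomic alteration (A)",
      colour = "Grade"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(th)) {
    p <- p +
      ggplot2::geom_vline(xintercept = c(th$n1, th$n2), linetype = "dashed") +
      ggplot2::geom_hline(yintercept = c(th$a1, th$a2), linetype = "dashed")
  }
  p
}

#' @export
tidy.g2i_scores <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.g2i_scores <- function(x, ...) {
  tibble(
    n = nrow(x),
    mean_A = mean(x$A), min_A = min(x$A), max_A = max(x$A),
    mean_N = mean(x$N), min_N = min(x$N), max_N = max(x$N),
    n_grade1 = sum(x$grade == 1L),
    n_grade2 = sum(x$grade == 2L),
    n_grade3 = sum(x$grade == 3L)
  )
}

#' @export
tidy.g2i_clusters <- function(x, ...) {
  x$assignment
}

#' @export
glance.g2i_clusters <- function(x, ...) {
  tibble(
    n = nrow(x$assignment),
    k = x$k,
    linkage = x$linkage,
    max_height = max(x$hclust$height)
  )
}

#' Plot a profile clustering as a 2-d MDS embedding
#'
#' Classical multidimensional scaling of the profile distance matrix,
#' coloured by cluster.
#'
#' @param object A `g2i_clusters` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.g2i_clusters <- function(object, ...) {
  xy <- cmdscale(object$distances, k = 2)
  df <- tibble(
    mds1 = xy[, 1], mds2 = xy[, 2],
    cluster = factor(object$assignment$cluster)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mds1, y = .data$mds2, colour = .data$cluster
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "MDS 1", y = "MDS 2", colour = "Cluster") +
    ggplot2::theme_minimal()
}

#' Plot one genomic profile
#'
#' Per-clone log2 ratios along the genome (clones in map order, faceted by
#' chromosome), with the smoothed fit overlaid when present and clones
#' coloured by GNL status when present.
#'
#' @param profiles Long profile tibble (one or more samples).
#' @param clone_map Clone map the profiles are aligned to.
#' @param sample Sample id to plot (default: first).
#' @param chromosomes Chromosomes to show (default: all autosomes).
#' @return A ggplot.
#' @export
plot_profile <- function(profiles, clone_map, sample = NULL,
                         chromosomes = AUTOSOMES) {
  sample <- sample %||% profiles$sample_id[1]
  df <- profiles %>%
    filter(.data$sample_id == sample) %>%
    mutate(
      chromosome = clone_map$chromosome[match(.data$clone_id, clone_map$clone_id)],
      index = match(.data$clone_id, clone_map$clone_id)
    ) %>%
    filter(.data$chromosome %in% chromosomes) %>%
    mutate(chromosome = factor(.data$chromosome, levels = CHROMOSOMES))
  aes_pt <- if ("status" %in% names(df)) {
    ggplot2::aes(x = .data$index, y = .data$log2, colour = factor(.data$status))
  } else {
    ggplot2::aes(x = .data$index, y = .data$log2)
  }
  p <- ggplot2::ggplot(df, aes_pt) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::facet_grid(. ~ chromosome, scales = "free_x", space = "free_x") +
    ggplot2::labs(
      x = "Clone (genome order)", y = "log2 ratio",
      colour = "GNL", title = sample
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.spacing = ggplot2::unit(0.1, "lines")
    )
  if ("smoothed" %in% names(df)) {
    p <- p + ggplot2::geom_step(
      ggplot2::aes(y = .data$smoothed),
      colour = "black", linewidth = 0.4
    )
  }
  p
}

#' Frequency plot of copy-number variation
#'
#' Per-clone gain (up) and loss (down) frequencies along the genome,
#' faceted by group when the frequency profile is stratified — the standard
#' summary of each genomic cluster's dominant changes.
#'
#' @param freq A [frequency_profile()] tibble.
#' @param clone_map Clone map the frequencies are aligned to.
#' @return A ggplot.
#' @export
plot_frequency <- function(freq, clone_map) {
  df <- freq %>%
    mutate(index = match(.data$clone_id, clone_map$clone_id))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$gain_frac), fill = "firebrick", alpha = 0.7) +
    ggplot2::geom_area(ggplot2::aes(y = -.data$loss_frac), fill = "steelblue", alpha = 0.7) +
    ggplot2::labs(x = "Clone (genome order)", y = "Loss | gain frequency") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
  if ("group" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~group)
  }
  p
}
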