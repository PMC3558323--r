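#' Built-in human chromosome-arm table
#'
#' Approximate human chromosome lengths and centromere positions (GRCh37
#' scale, in base pairs), used to partition clones into p and q arms.  The
#' five acrocentric chromosomes (13, 14, 15, 21, 22) are flagged: their short
#' arms carry essentially no unique sequence, so simulated clone maps place
#' no clones there and the per-arm average behind the instability index runs
#' over the 39 autosomal arms that carry clones.  Coordinates are otherwise
#' treated as opaque; any arm table with the same columns can be substituted.
#'
#' @return A tibble with columns `chromosome`, `centromere_position`,
#'   `length` (both in bp) and `acrocentric` (logical).
#' @export
#' @examples
#' human_arm_table()
human_arm_table <- function() {
  tbl <- tibble(
    chromosome = CHROMOSOMES,
    centromere_position = 1e6 * c(
      125, 93, 91, 50, 48, 61, 60, 45, 49, 40, 53, 36,
      18, 17, 19, 37, 24, 17, 26, 28, 13, 15, 61, 12
    ),
    length = 1e6 * c(
      249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
      115, 107, 102, 90, 81, 78, 59, 63, 48, 51, 155, 59
    ),
    acrocentric = CHROMOSOMES %in% c("13", "14", "15", "21", "22")
  )
  validate_arm_table(tbl)
  tbl
}

validate_arm_table <- function(arm_table) {
  stopifnot(is.data.frame(arm_table))
  need <- c("chromosome", "centromere_position", "length")
  missing_cols <- setdiff(need, names(arm_table))
  if (length(missing_cols) > 0) {
    abort(paste0("Arm table is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  check_chromosomes(arm_table$chromosome, "arm table")
  if (anyDuplicated(arm_table$chromosome)) {
    abort("Arm table has duplicated chromosome entries")
  }
  with(arm_table, {
    if (any(!(centromere_position > 0 & centromere_position < length))) {
      abort("Arm table requires 0 < centromere_position < length for every chromosome")
    }
  })
  invisible(arm_table)
}

#' Assign clones to chromosome arms
#'
#' A clone is assigned to the arm containing its midpoint, so a clone
#' spanning the centromere lands deterministically on one side.
#'
#' @param clone_map A clone map tibble (see [read_clone_map()]).
#' @param arm_table An arm table; defaults to [human_arm_table()].
#' @return The clone map with an `arm` column (`"p"` or `"q"`).
#' @export
assign_arms <- function(clone_map, arm_table = human_arm_table()) {
  validate_arm_table(arm_table)
  missing_chr <- setdiff(unique(clone_map$chromosome), arm_table$chromosome)
  if (length(missing_chr) > 0) {
    abort(paste0(
      "Chromosome(s) absent from the arm table: ",
      paste(missing_chr, collapse = ", ")
    ))
  }
  cen <- setNames(arm_table$centromere_position, arm_table$chromosome)
  mid <- (clone_map$start + clone_map$end) / 2
  clone_map$arm <- unname(ifelse(mid < cen[as.character(clone_map$chromosome)], "p", "q"))
  clone_map
}
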