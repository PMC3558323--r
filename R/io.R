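# Readers and writers for the tab-delimited formats the pipeline consumes.
# All files are UTF-8 TSV with '#' comment lines.  Coordinates are 1-based,
# fully closed intervals (BAC clone spans), following cytogenetic convention.

read_tsv_quiet <- function(path, col_types = NULL) {
  readr::read_tsv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = col_types
  )
}

#' Read a clone map
#'
#' The clone map is the genomic scaffold every profile is aligned to: one row
#' per BAC clone with its chromosome and 1-based closed span.  Rows may be in
#' any order in the file; the returned map is always in genome order
#' (chromosome 1-22, X, Y, then start position).
#'
#' @param path Path to a TSV with header columns `clone_id`, `chromosome`,
#'   `start`, `end` (comment lines starting with `#` are ignored).
#' @param arm_table Optional arm table used to assign an `arm` column via
#'   [assign_arms()]; `NULL` leaves arms unassigned.
#' @return A tibble with columns `clone_id`, `chromosome`, `start`, `end`
#'   and (if an arm table was given) `arm`.
#' @export
read_clone_map <- function(path, arm_table = human_arm_table()) {
  raw <- read_tsv_quiet(path, col_types = readr::cols(
    clone_id = readr::col_character(),
    chromosome = readr::col_character(),
    start = readr::col_character(),
    end = readr::col_character()
  ))
  need <- c("clone_id", "chromosome", "start", "end")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Clone map is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (col in c("start", "end")) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "Non-numeric %s coordinate in clone map at data line %d (clone_id %s)",
        col, bad[1], raw$clone_id[bad[1]]
      ))
    }
    raw[[col]] <- num
  }
  bad_chr <- which(!(raw$chromosome %in% CHROMOSOMES))
  if (length(bad_chr) > 0) {
    abort(sprintf(
      "Unknown chromosome label \"%s\" in clone map at data line %d",
      raw$chromosome[bad_chr[1]], bad_chr[1]
    ))
  }
  dup <- raw$clone_id[duplicated(raw$clone_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate clone_id in clone map: ", paste(unique(dup), collapse = ", ")))
  }
  if (any(raw$end < raw$start)) {
    abort("Clone map contains clones with end < start")
  }
  map <- raw %>%
    arrange(chrom_rank(.data$chromosome), .data$start) %>%
    as_tibble()
  if (!is.null(arm_table)) {
    map <- assign_arms(map, arm_table)
  }
  map
}

#' @rdname read_clone_map
#' @param clone_map Clone map tibble to write.
#' @export
write_clone_map <- function(clone_map, path) {
  readr::write_tsv(clone_map, path)
  invisible(path)
}

#' Read an arm table
#'
#' @param path TSV with columns `chromosome`, `centromere_position`, `length`
#'   and optionally `acrocentric`.
#' @return A validated arm table tibble.
#' @export
read_arm_table <- function(path) {
  tbl <- read_tsv_quiet(path)
  validate_arm_table(tbl)
  as_tibble(tbl)
}

#' Read a matrix of normalized log2 ratios
#'
#' The file is wide — first column `clone_id`, one column per sample — and is
#' returned long and aligned to the clone map: every sample has exactly one
#' row per clone of the map, in genome order, with `NA` for clones absent
#' from the file.  Clones in the file but not in the map are dropped with a
#' warning.
#'
#' @param path Path to the TSV.
#' @param clone_map Clone map the profiles are aligned to.
#' @return A long tibble with columns `sample_id`, `clone_id`, `log2`.
#' @export
read_log2_table <- function(path, clone_map) {
  raw <- read_tsv_quiet(path)
  if (names(raw)[1] != "clone_id") {
    abort("Log2 table must have clone_id as its first column")
  }
  unknown <- setdiff(raw$clone_id, clone_map$clone_id)
  if (length(unknown) > 0) {
    warn(sprintf(
      "Dropping %d clone(s) absent from the clone map (e.g. %s)",
      length(unknown), unknown[1]
    ))
    raw <- raw[raw$clone_id %in% clone_map$clone_id, ]
  }
  samples <- setdiff(names(raw), "clone_id")
  if (length(samples) == 0) abort("Log2 table has no sample columns")
  for (s in samples) {
    if (!any(is.finite(raw[[s]]))) {
      abort(sprintf("Sample column \"%s\" has no finite values", s))
    }
  }
  long <- raw %>%
    tidyr::pivot_longer(-"clone_id", names_to = "sample_id", values_to = "log2")
  align_profiles(long, clone_map, value = "log2")
}

# Align a long (sample_id, clone_id, value) tibble to clone-map order,
# completing missing clones with NA.
align_profiles <- function(long, clone_map, value = "log2") {
  grid <- tidyr::expand_grid(
    sample_id = unique(long$sample_id),
    clone_id = clone_map$clone_id
  )
  out <- grid %>%
    left_join(long[, c("sample_id", "clone_id", value)],
      by = c("sample_id", "clone_id")
    ) %>%
    mutate(.order = match(.data$clone_id, clone_map$clone_id)) %>%
    arrange(.data$sample_id, .data$.order) %>%
    select(-".order")
  out[[value]][!is.finite(out[[value]])] <- NA_real_
  out
}

#' @rdname read_log2_table
#' @param profiles Long profile tibble (`sample_id`, `clone_id`, value column).
#' @param value Name of the value column to write (`"log2"`, `"smoothed"` or
#'   `"status"`).
#' @export
write_log2_table <- function(profiles, path, value = "log2") {
  wide <- profiles %>%
    select("clone_id", "sample_id", dplyr::all_of(value)) %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = dplyr::all_of(value))
  readr::write_tsv(wide, path)
  invisible(path)
}

clinical_alphabets <- list(
  node_status = c("pN0", "pN+"),
  age_group = c("<=55", ">55"),
  sbr_grade = c("1", "2", "3"),
  hr_status = c("+", "-"),
  npi_class = c("1", "2", "3", "4"),
  mib1 = c("<20%", ">=20%"),
  intrinsic_class = c("LA", "LB", "HER2", "Basal", "unclassified")
)

#' Read a clinical annotation table
#'
#' One row per sample.  `relapse` must be 0/1 and `follow_up` (months)
#' positive; the categorical columns are checked against their fixed
#' alphabets (e.g. `node_status` in pN0/pN+, `mib1` in <20%/>=20%).  Optional
#' fields may be empty, which is kept as an explicit `NA`.
#'
#' @param path Path to the TSV.
#' @return A tibble of validated clinical records.
#' @export
read_clinical_table <- function(path) {
  tbl <- read_tsv_quiet(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    .default = readr::col_character()
  ))
  if (!all(c("sample_id", "relapse", "follow_up") %in% names(tbl))) {
    abort("Clinical table requires sample_id, relapse and follow_up columns")
  }
  tbl$relapse <- suppressWarnings(as.integer(tbl$relapse))
  if (any(!tbl$relapse %in% c(0L, 1L) | is.na(tbl$relapse))) {
    abort("relapse must be 0 or 1 for every sample")
  }
  tbl$follow_up <- suppressWarnings(as.numeric(tbl$follow_up))
  if (any(is.na(tbl$follow_up) | tbl$follow_up <= 0)) {
    abort("follow_up must be a positive number of months for every sample")
  }
  if ("tp53_altered" %in% names(tbl)) {
    tbl$tp53_altered <- suppressWarnings(as.integer(tbl$tp53_altered))
    if (any(!is.na(tbl$tp53_altered) & !tbl$tp53_altered %in% c(0L, 1L))) {
      abort("tp53_altered must be 0, 1 or missing")
    }
  }
  if ("size_mm" %in% names(tbl)) {
    tbl$size_mm <- suppressWarnings(as.numeric(tbl$size_mm))
  }
  for (col in intersect(names(clinical_alphabets), names(tbl))) {
    vals <- tbl[[col]]
    bad <- !is.na(vals) & !(vals %in% clinical_alphabets[[col]])
    if (any(bad)) {
      abort(sprintf(
        "Unknown %s category \"%s\" (allowed: %s)",
        col, vals[bad][1], paste(clinical_alphabets[[col]], collapse = ", ")
      ))
    }
  }
  as_tibble(tbl)
}

#' @rdname read_clinical_table
#' @param clinical Clinical tibble to write.
#' @export
write_clinical_table <- function(clinical, path) {
  readr::write_tsv(clinical, path)
  invisible(path)
}
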