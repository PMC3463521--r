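# karyotype classification from per-chromosome measurements

# basic structural validation shared by the reader and the classifiers
validate_measurements <- function(measurements) {
  required <- c(
    "cell_id", "chrom_index", "homolog_id", "relative_length", "arm_ratio"
  )
  missing <- setdiff(required, names(measurements))
  if (length(missing) > 0) {
    abort_schema(sprintf(
      "measurement table is missing column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  if (!"has_5S_signal" %in% names(measurements)) {
    measurements$has_5S_signal <- NA
  }
  measurements <- as_tibble(measurements)
  measurements$has_5S_signal <- as.logical(measurements$has_5S_signal)

  .check_rows <- function(ok, col, why) {
    if (any(!ok)) {
      abort_schema(sprintf(
        "row %d, column %s: %s", which(!ok)[1], col, why
      ))
    }
  }
  .check_rows(
    is.finite(measurements$relative_length) & measurements$relative_length > 0,
    "relative_length", "relative length must be > 0"
  )
  .check_rows(
    is.finite(measurements$arm_ratio) & measurements$arm_ratio >= 1,
    "arm_ratio", "arm ratio must be >= 1 (long arm / short arm)"
  )
  .check_rows(
    measurements$chrom_index %in% 1:13,
    "chrom_index", "chromosome index must be an integer 1-13"
  )
  .check_rows(
    measurements$homolog_id %in% 1:2,
    "homolog_id", "homolog id must be 1 or 2"
  )
  measurements
}

#' Classify every chromosome of a measurement table
#'
#' Adds the Levan centromere class, the large/small size class and the
#' compact Levan code to each measured chromosome.
#'
#' @param measurements a data frame with columns `cell_id`, `chrom_index`,
#'   `homolog_id`, `relative_length`, `arm_ratio` and optionally
#'   `has_5S_signal` (see [read_measurements()]).
#' @param size_cutoff relative-length threshold (percent) between small and
#'   large chromosomes.
#' @return The input as a tibble with columns `centromere_class`,
#'   `size_class` and `code` appended.
#' @examples
#' cells <- read_measurements(example_path("idiogram_measurements.csv"))
#' classify_chromosomes(cells)
#' @export
classify_chromosomes <- function(measurements, size_cutoff = 7) {
  measurements <- validate_measurements(measurements)
  measurements |>
    mutate(
      centromere_class = classify_centromere(.data$arm_ratio),
      size_class = classify_size(.data$relative_length, cutoff = size_cutoff),
      code = levan_code(.data$centromere_class, .data$size_class)
    )
}

# assign a focal code within a homolog slot: the translocation moved the
# chromosome-1 short arm, so translocated members are strongly acentric
# while normal members are solidly metacentric; hard Levan boundaries are
# not used here because the T (AR ~7.1) and St (AR ~3.4) means sit close to
# the 7.0 and 3.0 cuts and measurement noise would straddle them
.assign_chr1_code <- function(centromere_class, arm_ratio, cell_id) {
  ifelse(
    centromere_class == "metacentric", "M",
    ifelse(arm_ratio >= 3, "T", NA_character_)
  )
}

.assign_chr6_code <- function(centromere_class) {
  ifelse(centromere_class == "metacentric", "m", "St")
}

#' Karyotype a cell from its chromosome measurements
#'
#' Classifies all chromosomes of each cell (26 expected, 2n = 26), locates
#' the four focal chromosomes (pairs no. 1 and no. 6), assigns their focal
#' codes and returns the karyomorph per cell. Chromosomes carrying a 5S
#' rDNA signal are forced into the chromosome-1 slot — the marker sits on
#' both no. 1 homologs in every karyomorph — and the pair numbering of the
#' measurement table is used otherwise.
#'
#' The per-cell relative-length total is checked on the distinct-morphology
#' scale used by published idiograms: homomorphic pairs contribute their
#' mean once, the focal heteromorphic homologs contribute singly; the total
#' must be near 100 percent.
#'
#' @inheritParams classify_chromosomes
#' @param rl_tolerance allowed deviation of the per-cell distinct-morphology
#'   relative-length total from 100 percent before a warning is issued.
#' @return A tibble with one row per cell: `cell_id`, `karyomorph`,
#'   `chr1_pair`, `chr6_pair`, `balanced`, `rl_total`, plus a `chromosomes`
#'   list-column holding each cell's full classification table.
#' @examples
#' cells <- read_measurements(example_path("idiogram_measurements.csv"))
#' classify_karyotype(cells)
#' @export
classify_karyotype <- function(measurements, size_cutoff = 7, rl_tolerance = 5) {
  classified <- classify_chromosomes(measurements, size_cutoff = size_cutoff)
  cells <- split(classified, classified$cell_id)
  rows <- purrr::map(cells, function(cell) {
    .karyotype_one_cell(cell, rl_tolerance = rl_tolerance)
  })
  bind_rows(rows)
}

.karyotype_one_cell <- function(cell, rl_tolerance = 5) {
  id <- cell$cell_id[1]
  if (nrow(cell) != 26) {
    abort_schema(sprintf(
      "cell '%s': expected 26 chromosomes (2n = 26), got %d", id, nrow(cell)
    ))
  }

  flags <- cell$has_5S_signal
  use_flags <- any(!is.na(flags) & flags)
  if (use_flags) {
    chr1_idx <- which(!is.na(flags) & flags)
    if (length(chr1_idx) != 2) {
      abort_schema(sprintf(
        "cell '%s': %d chromosomes carry a 5S signal; the marker must tag exactly the two no. 1 homologs",
        id, length(chr1_idx)
      ))
    }
  } else {
    chr1_idx <- which(cell$chrom_index == 1)
  }
  chr6_idx <- setdiff(which(cell$chrom_index == 6), chr1_idx)
  if (length(chr6_idx) < 2) {
    # a flagged chromosome was recorded under pair 6: backfill from pair 1
    chr6_idx <- c(chr6_idx, setdiff(which(cell$chrom_index == 1), chr1_idx))
  }
  if (length(chr1_idx) != 2 || length(chr6_idx) != 2) {
    abort_schema(sprintf(
      "cell '%s': could not locate two chromosomes for each focal pair", id
    ))
  }

  chr1_codes <- .assign_chr1_code(
    as.character(cell$centromere_class[chr1_idx]), cell$arm_ratio[chr1_idx]
  )
  if (any(is.na(chr1_codes))) {
    amb <- chr1_idx[is.na(chr1_codes)]
    abort_model(sprintf(
      "cell '%s': ambiguous chromosome-1 homolog (arm ratio %s is submetacentric, neither M-like nor T-like)",
      id, paste(format(cell$arm_ratio[amb]), collapse = ", ")
    ))
  }
  chr6_codes <- .assign_chr6_code(as.character(cell$centromere_class[chr6_idx]))

  focal_idx <- c(chr1_idx, chr6_idx)
  focal_code <- rep(NA_character_, 26)
  focal_code[chr1_idx] <- chr1_codes
  focal_code[chr6_idx] <- chr6_codes
  cell$focal_code <- focal_code

  # distinct-morphology relative-length total: focal heteromorphic homologs
  # count singly, every other pair counts once by its mean
  nonfocal <- cell[-focal_idx, ]
  pair_means <- tapply(nonfocal$relative_length, nonfocal$chrom_index, mean)
  rl_total <- sum(cell$relative_length[focal_idx]) +
    sum(ifelse(
      # a homomorphic focal pair is also counted once
      rep(c(
        chr1_codes[1] == chr1_codes[2], chr6_codes[1] == chr6_codes[2]
      ), each = 2),
      -cell$relative_length[focal_idx] / 2, 0
    )) +
    sum(pair_means)
  if (abs(rl_total - 100) > rl_tolerance) {
    warn(sprintf(
      "cell '%s': distinct-morphology relative-length total %.2f deviates from 100 by more than %.1f",
      id, rl_total, rl_tolerance
    ))
  }

  label <- karyomorph_from_codes(chr1_codes, chr6_codes)
  tibble(
    cell_id = id,
    karyomorph = label,
    chr1_pair = paste(sort_codes(chr1_codes), collapse = ""),
    chr6_pair = paste(sort_codes(chr6_codes), collapse = ""),
    balanced = is_balanced_label(label),
    rl_total = rl_total,
    chromosomes = list(cell)
  )
}
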