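# seeded generators for every input the pipeline consumes

#' Built-in idiogram moment tables
#'
#' Per-chromosome mean and SD of relative length and arm ratio for the two
#' measured karyomorphs (the normal type I and the translocation
#' heterozygote type IV), expanded to one row per homolog, with the
#' published Levan code and the 5S rDNA carrier flag.
#'
#' @return A tibble with columns `karyomorph`, `chrom_index`, `homolog_id`,
#'   `rl_mean`, `rl_sd`, `ar_mean`, `ar_sd`, `code`, `carries_5s`.
#' @examples
#' builtin_idiograms()
#' @export
builtin_idiograms <- function() {
  readr::read_csv(
    example_path("idiogram_moments.csv"),
    col_types = readr::cols(
      karyomorph = readr::col_character(),
      chrom_index = readr::col_integer(),
      homolog_id = readr::col_integer(),
      rl_mean = readr::col_double(),
      rl_sd = readr::col_double(),
      ar_mean = readr::col_double(),
      ar_sd = readr::col_double(),
      code = readr::col_character(),
      carries_5s = readr::col_logical()
    )
  )
}

#' Generate per-cell chromosome measurements
#'
#' Draws noisy metaphase cells around an idiogram: relative lengths and arm
#' ratios come from lower-truncated normals (RL > 0, AR >= 1) at the
#' idiogram's moments; each cell's relative lengths are then rescaled so the
#' cell total equals the idiogram total, mimicking the normalisation a
#' measured cell undergoes; 5S flags are copied from the idiogram (both
#' chromosome-1 homologs carry the marker).
#'
#' @param karyomorph which karyomorph to simulate; must be present in
#'   `idiogram`.
#' @param n_cells number of cells (>= 1).
#' @param idiogram an idiogram moment table, by default
#'   [builtin_idiograms()].
#' @param seed integer seed; generation is fully deterministic given the
#'   seed and never touches the global RNG state.
#' @return A measurement tibble (columns `cell_id`, `chrom_index`,
#'   `homolog_id`, `relative_length`, `arm_ratio`, `has_5S_signal`) with
#'   `26 * n_cells` rows.
#' @examples
#' cells <- generate_cells("IV", n_cells = 3, seed = 1)
#' classify_karyotype(cells)
#' @export
generate_cells <- function(karyomorph, n_cells, idiogram = builtin_idiograms(),
                           seed) {
  if (n_cells < 1) abort_model("n_cells must be >= 1")
  spec <- filter(idiogram, .data$karyomorph == !!karyomorph)
  if (nrow(spec) == 0) {
    abort_model(sprintf("idiogram has no rows for karyomorph '%s'", karyomorph))
  }
  present <- sort(unique(spec$chrom_index))
  if (!identical(present, 1:13) || nrow(spec) != 26) {
    abort_schema(sprintf(
      "idiogram for '%s' must describe all 13 pairs (26 homologs); found %d rows",
      karyomorph, nrow(spec)
    ))
  }
  if (any(spec$rl_mean <= 0) || any(spec$rl_sd < 0) ||
      any(spec$ar_mean < 1) || any(spec$ar_sd < 0)) {
    abort_schema("idiogram moments out of range (means > 0, AR >= 1, SDs >= 0)")
  }
  target_total <- sum(spec$rl_mean)

  withr::with_seed(seed, {
    cells <- purrr::map(seq_len(n_cells), function(i) {
      rl <- rtruncnorm_lower(26, spec$rl_mean, spec$rl_sd, lower = 1e-6)
      ar <- rtruncnorm_lower(26, spec$ar_mean, spec$ar_sd, lower = 1)
      rl <- rl * target_total / sum(rl)
      tibble(
        cell_id = sprintf("%s_cell_%04d", karyomorph, i),
        chrom_index = spec$chrom_index,
        homolog_id = spec$homolog_id,
        relative_length = rl,
        arm_ratio = ar,
        has_5S_signal = spec$carries_5s
      )
    })
    bind_rows(cells)
  })
}

#' Generate population karyomorph counts
#'
#' Draws individuals from the viability-filtered random-union distribution
#' implied by a gamete pool ([zygote_frequencies()]), one multinomial draw
#' per population, and assigns sexes independently (autosomal polymorphism:
#' an even sex ratio, independent of karyomorph).
#'
#' @param f gamete-pool frequencies in the order `M/m`, `T/St`, `M/St`,
#'   `m/T`.
#' @param pop_sizes integer vector of individuals per population; names
#'   become population ids (defaults `pop_01`, ...).
#' @param viability named viability vector ([viability_map()]).
#' @param seed integer seed.
#' @param p_female probability an individual is female.
#' @return A count tibble (`population_id`, `sex`, `karyomorph`, `count`)
#'   covering every karyomorph in the surviving support, zeros included.
#' @examples
#' generate_counts(c(0.9, 0.06, 0.03, 0.01), pop_sizes = c(100, 50), seed = 7)
#' @export
generate_counts <- function(f, pop_sizes, viability = default_viability(),
                            seed, p_female = 0.5) {
  probs <- zygote_frequencies(f, viability)
  if (any(pop_sizes < 0)) abort_model("population sizes must be non-negative")
  ids <- names(pop_sizes) %||% sprintf("pop_%02d", seq_along(pop_sizes))

  withr::with_seed(seed, {
    pops <- purrr::map(seq_along(pop_sizes), function(i) {
      draw <- rmultinom(1, size = pop_sizes[i], prob = probs$prob)[, 1]
      females <- rbinom(length(draw), size = draw, prob = p_female)
      tibble(
        population_id = ids[i],
        sex = rep(c("female", "male"), each = length(draw)),
        karyomorph = rep(probs$karyomorph, 2),
        count = c(females, draw - females)
      )
    })
    bind_rows(pops)
  })
}

#' Generate heteromorphic-chromosome length tables
#'
#' Simulates absolute lengths (micrometres) of the four focal chromosomes
#' in a translocation heterozygote across cells. Each cell gets a lognormal
#' contraction/spread factor (metaphase cells vary about two-fold in total
#' length) applied to the base lengths, plus additive measurement noise,
#' truncated positive. The default base lengths satisfy exact arm-length
#' conservation (`l(1-2) + l(6-2) = l(1-1) + l(6-1)`), so the generator
#' samples from the null of the conservation test up to noise.
#'
#' @param n_cells number of cells.
#' @param base_lengths named numeric vector of base lengths for `1-1`,
#'   `1-2`, `6-1`, `6-2` in micrometres.
#' @param noise_sd additive measurement noise SD (micrometres).
#' @param cell_scale_sd SD of the per-cell lognormal scale factor (on the
#'   log scale).
#' @param seed integer seed.
#' @return A length tibble (`cell_id`, `chrom`, `length_um`).
#' @examples
#' arm_conservation_test(generate_lengths(10, seed = 1))
#' @export
generate_lengths <- function(n_cells,
                             base_lengths = c("1-1" = 6.5, "1-2" = 4.2,
                                              "6-1" = 2.5, "6-2" = 4.8),
                             noise_sd = 0.15, cell_scale_sd = 0.25, seed) {
  if (n_cells < 1) abort_model("n_cells must be >= 1")
  chroms <- c("1-1", "1-2", "6-1", "6-2")
  if (!all(chroms %in% names(base_lengths))) {
    abort_schema("base_lengths must name all of 1-1, 1-2, 6-1, 6-2")
  }
  if (any(base_lengths <= 0)) abort_schema("base lengths must be positive")

  withr::with_seed(seed, {
    cells <- purrr::map(seq_len(n_cells), function(i) {
      scale <- exp(rnorm(1, mean = 0, sd = cell_scale_sd))
      len <- rtruncnorm_lower(
        4, mean = unname(base_lengths[chroms]) * scale, sd = noise_sd,
        lower = 0.05
      )
      tibble(cell_id = i, chrom = chroms, length_um = len)
    })
    bind_rows(cells)
  })
}
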