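# frequency tables, gamete-pool maximum likelihood, arm-length conservation

# structural validation of a karyomorph count table
validate_counts <- function(counts) {
  required <- c("population_id", "sex", "karyomorph", "count")
  missing <- setdiff(required, names(counts))
  if (length(missing) > 0) {
    abort_schema(sprintf(
      "count table is missing column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  counts <- as_tibble(counts)
  bad_sex <- !counts$sex %in% c("male", "female")
  if (any(bad_sex)) {
    abort_schema(sprintf(
      "row %d, column sex: must be 'male' or 'female'", which(bad_sex)[1]
    ))
  }
  bad_n <- !is.finite(counts$count) | counts$count < 0 |
    counts$count != round(counts$count)
  if (any(bad_n)) {
    abort_schema(sprintf(
      "row %d, column count: must be a non-negative integer", which(bad_n)[1]
    ))
  }
  ok_label <- vapply(counts$karyomorph, function(l) {
    !inherits(try(codes_from_label(l), silent = TRUE), "try-error")
  }, logical(1))
  if (any(!ok_label)) {
    abort_schema(sprintf(
      "row %d, column karyomorph: unknown label '%s'",
      which(!ok_label)[1], counts$karyomorph[which(!ok_label)[1]]
    ))
  }
  counts
}

#' Karyomorph frequency table per population and pooled
#'
#' Computes per-population karyomorph frequencies (sexes pooled) and a
#' pooled row over all populations, with exact proportions plus the percent
#' column rounded half-up the way published frequency tables are printed.
#'
#' @param counts a karyomorph count table with columns `population_id`,
#'   `sex`, `karyomorph`, `count` (see [read_karyomorph_counts()]).
#' @param digits decimal places for the printed `percent` column.
#' @param include_pooled append a pooled row set with
#'   `population_id = "pooled"`.
#' @return A tibble with columns `population_id`, `karyomorph`, `n`,
#'   `total`, `freq` (exact proportion, `NA` for an empty population, which
#'   is flagged rather than an error) and `percent`.
#' @examples
#' freqs <- frequency_table(example_karyomorph_counts())
#' dplyr::filter(freqs, population_id == "pooled")
#' @export
frequency_table <- function(counts, digits = 1, include_pooled = TRUE) {
  counts <- validate_counts(counts)
  if (sum(counts$count) == 0) abort_model("count table has no individuals")
  labels <- sort_karyomorphs(unique(counts$karyomorph))

  per_pop <- counts |>
    group_by(.data$population_id, .data$karyomorph) |>
    summarise(n = sum(.data$count), .groups = "drop")
  grid <- tidyr::expand_grid(
    population_id = unique(counts$population_id), karyomorph = labels
  )
  out <- grid |>
    left_join(per_pop, by = c("population_id", "karyomorph")) |>
    mutate(n = dplyr::coalesce(.data$n, 0)) |>
    group_by(.data$population_id) |>
    mutate(total = sum(.data$n)) |>
    ungroup()

  if (include_pooled) {
    pooled <- out |>
      group_by(.data$karyomorph) |>
      summarise(n = sum(.data$n), .groups = "drop") |>
      mutate(population_id = "pooled", total = sum(.data$n))
    out <- bind_rows(out, pooled)
  }

  out |>
    mutate(
      freq = ifelse(.data$total > 0, .data$n / .data$total, NA_real_),
      percent = round_half_up(100 * .data$freq, digits),
      empty_population = .data$total == 0
    ) |>
    mutate(karyomorph = factor(.data$karyomorph, levels = labels)) |>
    arrange(match(.data$population_id, c(unique(counts$population_id), "pooled")),
            .data$karyomorph) |>
    mutate(karyomorph = as.character(.data$karyomorph))
}

#' Zygote karyomorph frequencies under random gamete union
#'
#' Given the frequencies of the four gametes produced by alternate and
#' adjacent-1 segregation — `M/m` (f1), `T/St` (f2), `M/St` (f3), `m/T`
#' (f4) — random union gives the nine balanced zygote types at
#' I: f1^2, II: 2 f1 f3, III: 2 f1 f4, IV: 2 f1 f2 + 2 f3 f4 (two distinct
#' unions are karyologically type IV), V: 2 f2 f3, VI: f3^2, VII: f4^2,
#' VIII: 2 f2 f4, IX: f2^2. An optional viability map filters and
#' renormalises to frequencies among the living.
#'
#' @param f numeric vector of four gamete frequencies in the order `M/m`,
#'   `T/St`, `M/St`, `m/T` (names optional); must sum to 1.
#' @param viability optional named viability vector ([viability_map()]).
#' @return A tibble with columns `karyomorph` and `prob`; attribute
#'   `surviving_mass` when a viability map was applied.
#' @examples
#' zygote_frequencies(c(0.9, 0.05, 0.03, 0.02))
#' @export
zygote_frequencies <- function(f, viability = NULL) {
  if (length(f) != 4) abort_model("f must hold four gamete frequencies")
  f <- unname(f)
  check_simplex(f, "gamete frequencies")
  prob <- c(
    I = f[1]^2,
    II = 2 * f[1] * f[3],
    III = 2 * f[1] * f[4],
    IV = 2 * f[1] * f[2] + 2 * f[3] * f[4],
    V = 2 * f[2] * f[3],
    VI = f[3]^2,
    VII = f[4]^2,
    VIII = 2 * f[2] * f[4],
    IX = f[2]^2
  )
  out <- tibble(karyomorph = names(prob), prob = unname(prob))
  if (!is.null(viability)) {
    v <- viability_of(viability, out$karyomorph)
    out$prob <- out$prob * v
    mass <- sum(out$prob)
    if (mass < 1e-12) abort_model("viability map leaves no surviving zygotes")
    out$prob <- out$prob / mass
    attr(out, "surviving_mass") <- mass
  }
  out
}

GAMETE_POOL_NAMES <- c("M/m", "T/St", "M/St", "m/T")

# negative log-likelihood in softmax parameterisation (z in R^3)
.gp_nll <- function(z, obs_counts, obs_labels, viability) {
  e <- exp(c(0, z))
  f <- e / sum(e)
  p <- zygote_frequencies(f, viability)
  probs <- p$prob[match(obs_labels, p$karyomorph)]
  if (any(probs <= 0 & obs_counts > 0)) return(Inf)
  -sum(obs_counts[obs_counts > 0] * log(probs[obs_counts > 0]))
}

#' Fit gamete-pool frequencies to observed karyomorph counts
#'
#' Maximum-likelihood estimation of the four gamete frequencies (`M/m`,
#' `T/St`, `M/St`, `m/T`) from a table of observed karyomorph counts, under
#' the random-union multinomial model of [zygote_frequencies()] restricted
#' and renormalised to the viable karyomorphs. The likelihood is maximised
#' over the 3-simplex by Nelder-Mead in a softmax parameterisation from a
#' deterministic grid of starting points.
#'
#' @param counts observed counts: a data frame with `karyomorph` and `count`
#'   columns (extra columns such as `population_id`/`sex` are pooled), or a
#'   named numeric vector.
#' @param viability named viability vector; the default lets only types I-V
#'   survive. Positive observed counts on karyomorphs the map declares
#'   inviable are a model error.
#' @return An object of class `gamete_pool_fit` with elements `estimates`
#'   (named frequencies), `log_likelihood` (multinomial frequency form,
#'   `sum(n log p)`), `expected` (expected counts per viable karyomorph),
#'   `observed`, `n`, `converged` and `boundary` (an estimate pinned to the
#'   simplex boundary). Supports [tidy()], [glance()], `print()` and
#'   [autoplot()].
#' @examples
#' fit <- fit_gamete_pool(example_karyomorph_counts())
#' tidy(fit)
#' glance(fit)
#' @export
fit_gamete_pool <- function(counts, viability = default_viability()) {
  if (is.numeric(counts) && !is.null(names(counts))) {
    counts <- tibble(karyomorph = names(counts), count = unname(counts))
  }
  if (!all(c("karyomorph", "count") %in% names(counts))) {
    abort_schema("counts must provide 'karyomorph' and 'count' columns")
  }
  obs <- counts |>
    group_by(.data$karyomorph) |>
    summarise(count = sum(.data$count), .groups = "drop")

  viable <- names(viability)[viability > 0]
  dead_obs <- obs$karyomorph[!obs$karyomorph %in% viable & obs$count > 0]
  if (length(dead_obs) > 0) {
    abort_model(sprintf(
      "observed individuals of karyomorph(s) %s, but the viability map declares them inviable",
      paste(dead_obs, collapse = ", ")
    ))
  }
  obs_labels <- sort_karyomorphs(viable)
  obs_counts <- obs$count[match(obs_labels, obs$karyomorph)]
  obs_counts[is.na(obs_counts)] <- 0
  n_total <- sum(obs_counts)
  if (n_total == 0) abort_model("no observed individuals to fit")

  # deterministic multi-start: centre plus every +/-2 logit corner
  starts <- as.matrix(expand.grid(z1 = c(-2, 0, 2), z2 = c(-2, 0, 2),
                                  z3 = c(-2, 0, 2)))
  fits <- apply(starts, 1, function(z0) {
    optim(z0, .gp_nll, obs_counts = obs_counts, obs_labels = obs_labels,
          viability = viability, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-12))
  })
  values <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(values)]]

  e <- exp(c(0, best$par))
  f <- setNames(e / sum(e), GAMETE_POOL_NAMES)
  p <- zygote_frequencies(unname(f), viability)
  expected <- setNames(
    n_total * p$prob[match(obs_labels, p$karyomorph)], obs_labels
  )

  structure(list(
    estimates = f,
    log_likelihood = -best$value,
    expected = expected,
    observed = setNames(obs_counts, obs_labels),
    n = n_total,
    converged = best$convergence == 0,
    boundary = any(f < 1e-5),
    viability = viability
  ), class = "gamete_pool_fit")
}

#' @export
print.gamete_pool_fit <- function(x, ...) {
  cat("Gamete-pool fit (random-union multinomial, viability-filtered)\n")
  cat(sprintf("  n = %d individuals, log-likelihood = %.4f%s%s\n", x$n,
              x$log_likelihood,
              if (x$converged) "" else " [did not converge]",
              if (x$boundary) " [boundary optimum]" else ""))
  est <- format(round(x$estimates, 4))
  for (g in names(x$estimates)) cat(sprintf("  f(%s) = %s\n", g, est[g]))
  invisible(x)
}

#' @describeIn fit_gamete_pool one row per gamete class with its estimated
#'   pool frequency.
#' @param x a `gamete_pool_fit` object.
#' @param ... unused.
#' @method tidy gamete_pool_fit
#' @export
tidy.gamete_pool_fit <- function(x, ...) {
  tibble(gamete = names(x$estimates), estimate = unname(x$estimates))
}

#' @describeIn fit_gamete_pool one-row model summary.
#' @method glance gamete_pool_fit
#' @export
glance.gamete_pool_fit <- function(x, ...) {
  tibble(
    log_likelihood = x$log_likelihood, n = x$n,
    converged = x$converged, boundary = x$boundary
  )
}

#' Paired test of arm-length conservation
#'
#' A reciprocal translocation exchanges segments but conserves total
#' chromatin: per cell, the summed length of the four heteromorphic
#' chromosomes (no. 1 and no. 6 homologs) should equal twice the summed
#' length of the two normal homologs. Computes both per-cell sums and the
#' paired two-sided t-test across cells.
#'
#' @param lengths a length table with columns `cell_id`, `chrom` (one of
#'   `1-1`, `1-2`, `6-1`, `6-2`) and `length_um` (see
#'   [read_length_table()]).
#' @return A one-row tibble: `n_cells`, `mean_het_sum` and `mean_norm_sum`
#'   (micrometres), `mean_difference`, `statistic`, `df`, `p_value`.
#' @examples
#' arm_conservation_test(example_length_table())
#' @export
arm_conservation_test <- function(lengths) {
  lengths <- validate_lengths(lengths)
  wide <- lengths |>
    tidyr::pivot_wider(names_from = "chrom", values_from = "length_um")
  if (nrow(wide) < 2) {
    abort_model("arm-length conservation test needs at least 2 cells")
  }
  s_het <- wide[["1-1"]] + wide[["1-2"]] + wide[["6-1"]] + wide[["6-2"]]
  s_norm <- 2 * (wide[["1-1"]] + wide[["6-1"]])
  if (all(s_het == s_norm)) {
    # degenerate but well-defined case: zero difference in every cell
    return(tibble(
      n_cells = nrow(wide), mean_het_sum = mean(s_het),
      mean_norm_sum = mean(s_norm), mean_difference = 0,
      statistic = 0, df = nrow(wide) - 1, p_value = 1
    ))
  }
  tt <- t.test(s_het, s_norm, paired = TRUE)
  tibble(
    n_cells = nrow(wide),
    mean_het_sum = mean(s_het),
    mean_norm_sum = mean(s_norm),
    mean_difference = mean(s_het - s_norm),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

validate_lengths <- function(lengths) {
  required <- c("cell_id", "chrom", "length_um")
  missing <- setdiff(required, names(lengths))
  if (length(missing) > 0) {
    abort_schema(sprintf(
      "length table is missing column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  lengths <- as_tibble(lengths)
  bad_chrom <- !lengths$chrom %in% c("1-1", "1-2", "6-1", "6-2")
  if (any(bad_chrom)) {
    abort_schema(sprintf(
      "row %d, column chrom: must be one of 1-1, 1-2, 6-1, 6-2",
      which(bad_chrom)[1]
    ))
  }
  bad_len <- !is.finite(lengths$length_um) | lengths$length_um <= 0
  if (any(bad_len)) {
    abort_schema(sprintf(
      "row %d, column length_um: lengths must be positive", which(bad_len)[1]
    ))
  }
  lengths
}
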