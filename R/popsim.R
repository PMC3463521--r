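# forward-time simulation of karyomorph frequencies under random mating,
# quadrivalent segregation and zygote viability selection

# normalise an init specification (named vector or karyomorph/count tibble)
# to a named frequency vector
.as_freqs <- function(init) {
  if (is.data.frame(init)) {
    col <- intersect(c("count", "freq", "prob"), names(init))[1]
    if (is.na(col) || !"karyomorph" %in% names(init)) {
      abort_schema("init must have a 'karyomorph' column and a 'count' or 'freq' column")
    }
    x <- tapply(init[[col]], init$karyomorph, sum)
    init <- setNames(as.numeric(x), names(x))
  }
  if (is.null(names(init)) || any(init < 0) || sum(init) <= 0) {
    abort_model("initial state must be non-negative named counts or frequencies")
  }
  # canonicalise labels so "MT/mSt" and "IV" merge
  labs <- vapply(names(init), function(l) karyomorph_label(codes_from_label(l)),
                 character(1), USE.NAMES = FALSE)
  x <- tapply(unname(init), labs, sum)
  setNames(as.numeric(x), names(x)) / sum(init)
}

# population gamete pool: frequency-weighted mixture of the genotypes'
# gamete distributions
gamete_pool <- function(freqs, params = segregation_params()) {
  pools <- purrr::map2(names(freqs), unname(freqs), function(lab, f) {
    if (f <= 0) return(NULL)
    g <- gamete_distribution(lab, params)
    tibble(gamete = g$gamete, prob = g$prob * f)
  })
  bind_rows(pools) |>
    group_by(.data$gamete) |>
    summarise(prob = sum(.data$prob), .groups = "drop")
}

#' One generation of the deterministic recursion
#'
#' Random union of the population gamete pool with itself (panmixia,
#' non-overlapping generations), followed by viability selection and
#' renormalisation over the surviving mass.
#'
#' @param freqs named vector of current karyomorph frequencies (any labels
#'   accepted by [codes_from_label()]).
#' @param params segregation-mode probabilities ([segregation_params()]).
#' @param viability named viability vector ([viability_map()]).
#' @return Named frequency vector for the next generation. If every zygote
#'   is inviable the vector is all zero and carries attribute
#'   `extinct = TRUE`.
#' @examples
#' step_population(c(I = 0.9, IV = 0.1))
#' @export
step_population <- function(freqs, params = segregation_params(),
                            viability = default_viability()) {
  freqs <- .as_freqs(freqs)
  pool <- gamete_pool(freqs, params)
  grid <- tidyr::expand_grid(i = seq_len(nrow(pool)), j = seq_len(nrow(pool)))
  labs <- vapply(seq_len(nrow(grid)), function(k) {
    karyomorph_label(c(
      gamete_codes(pool$gamete[grid$i[k]]),
      gamete_codes(pool$gamete[grid$j[k]])
    ))
  }, character(1))
  zyg <- tapply(pool$prob[grid$i] * pool$prob[grid$j], labs, sum)
  out <- setNames(as.numeric(zyg), names(zyg))
  out <- out * viability_of(viability, names(out))
  mass <- sum(out)
  if (mass < 1e-12) {
    out[] <- 0
    attr(out, "extinct") <- TRUE
    return(out)
  }
  out <- out[out > 0] / mass
  attr(out, "extinct") <- FALSE
  out
}

#' Simulate karyomorph frequencies forward in time
#'
#' Runs the random-mating / viability-selection recursion for a fixed number
#' of non-overlapping generations, either deterministically (infinite
#' population: expected frequencies) or with multinomial reproduction in a
#' finite population of `N` individuals.
#'
#' @param init initial state: named counts/frequencies or a tibble with
#'   `karyomorph` and `count` (or `freq`) columns.
#' @param generations number of generations to simulate (>= 1).
#' @param params segregation-mode probabilities ([segregation_params()]).
#' @param viability named viability vector ([viability_map()]).
#' @param mode `"deterministic"` or `"finite"`.
#' @param N population size for finite mode; defaults to the total of the
#'   initial counts.
#' @param seed integer seed, required in finite mode; the simulation never
#'   touches the global RNG state.
#' @return A tibble with columns `generation` (0 = initial state),
#'   `karyomorph`, `freq`, and in finite mode `count`. An `extinct`
#'   attribute flags the first generation (if any) in which no viable
#'   offspring could be formed.
#' @examples
#' simulate_generations(c(I = 0.99, IV = 0.01), generations = 3)
#' @export
simulate_generations <- function(init, generations, params = segregation_params(),
                                 viability = default_viability(),
                                 mode = c("deterministic", "finite"),
                                 N = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (generations < 1) abort_model("generations must be >= 1")
  freqs0 <- .as_freqs(init)

  if (mode == "finite") {
    if (is.null(seed)) abort_model("finite-population simulation requires an integer seed")
    if (is.null(N)) {
      N <- if (is.data.frame(init) && "count" %in% names(init)) {
        sum(init$count)
      } else if (!is.data.frame(init) && all(init == round(init)) && sum(init) > 1) {
        sum(init)
      } else {
        abort_model("finite mode needs N (or integer counts as init)")
      }
    }
    counts <- round(freqs0 * N)
  }

  rows <- list(tibble(
    generation = 0L, karyomorph = names(freqs0), freq = unname(freqs0)
  ))
  if (mode == "finite") rows[[1]]$count <- as.integer(round(freqs0 * N))

  extinct_at <- NA_integer_
  run <- function() {
    freqs <- freqs0
    for (g in seq_len(generations)) {
      nxt <- step_population(freqs, params, viability)
      if (isTRUE(attr(nxt, "extinct"))) {
        extinct_at <<- g
        break
      }
      if (mode == "finite") {
        draw <- rmultinom(1, size = N, prob = unname(nxt))[, 1]
        keep <- draw > 0
        freqs <- setNames(draw[keep] / N, names(nxt)[keep])
        rows[[g + 1]] <<- tibble(
          generation = g, karyomorph = names(freqs), freq = unname(freqs),
          count = as.integer(draw[keep])
        )
      } else {
        freqs <- setNames(unname(nxt), names(nxt))
        rows[[g + 1]] <<- tibble(
          generation = g, karyomorph = names(freqs), freq = unname(freqs)
        )
      }
    }
  }
  if (mode == "finite") withr::with_seed(seed, run()) else run()

  out <- bind_rows(rows)
  attr(out, "extinct") <- extinct_at
  out
}

#' Simulate the single-migrant dispersal scenario
#'
#' One translocation-carrying migrant enters a population otherwise fixed
#' for the resident karyomorph. In the deterministic mode the migrant is a
#' single individual among `2 * N` and cannot mate with itself, so the first
#' generation mixes migrant-by-resident offspring (a fraction `1/N` of all
#' matings) with resident-by-resident offspring; from the second generation
#' on the population follows the panmictic pool recursion
#' ([step_population()]). In finite mode the migrant simply replaces one
#' resident in a population of `2 * N` individuals and reproduction is
#' multinomial.
#'
#' @param migrant,resident karyomorph labels (defaults: a type IV migrant
#'   into a type I population).
#' @param N half the population size: the deterministic migrant enters at
#'   frequency `1 / (2 N)`.
#' @inheritParams simulate_generations
#' @return A trajectory tibble as from [simulate_generations()].
#' @examples
#' simulate_dispersal(N = 50, generations = 3,
#'                    params = segregation_params(0.9, 0.1, 0))
#' @export
simulate_dispersal <- function(migrant = "IV", resident = "I", N = 50,
                               generations = 2,
                               params = segregation_params(),
                               viability = default_viability(),
                               mode = c("deterministic", "finite"),
                               seed = NULL) {
  mode <- match.arg(mode)
  if (generations < 1) abort_model("generations must be >= 1")
  init <- setNames(c(2 * N - 1, 1), c(resident, migrant))

  if (mode == "finite") {
    return(simulate_generations(
      init, generations, params, viability,
      mode = "finite", N = 2 * N, seed = seed
    ))
  }

  freqs0 <- .as_freqs(init)
  f1_mig <- cross_karyomorphs(migrant, resident, params, viability)
  f1_res <- cross_karyomorphs(resident, resident, params, viability)
  if (isTRUE(attr(f1_mig, "sterile")) && isTRUE(attr(f1_res, "sterile"))) {
    abort_model("dispersal scenario is sterile: no cross leaves viable offspring")
  }
  w <- 1 / N # fraction of matings involving the single migrant
  f1 <- bind_rows(
    mutate(f1_mig, prob = .data$prob * w),
    mutate(f1_res, prob = .data$prob * (1 - w))
  ) |>
    group_by(.data$karyomorph) |>
    summarise(prob = sum(.data$prob), .groups = "drop")
  freqs <- setNames(f1$prob / sum(f1$prob), f1$karyomorph)

  rows <- list(
    tibble(generation = 0L, karyomorph = names(freqs0), freq = unname(freqs0)),
    tibble(generation = 1L, karyomorph = names(freqs), freq = unname(freqs))
  )
  g <- 2L
  while (g <= generations) {
    nxt <- step_population(freqs, params, viability)
    if (isTRUE(attr(nxt, "extinct"))) break
    freqs <- setNames(unname(nxt), names(nxt))
    rows[[g + 1]] <- tibble(
      generation = g, karyomorph = names(freqs), freq = unname(freqs)
    )
    g <- g + 1L
  }
  bind_rows(rows)
}

#' Deterministic reachability of karyomorphs after a migration event
#'
#' Set-valued recursion over generations: the F1 set contains the viable
#' offspring karyomorphs of the migrant-by-resident cross; each later
#' generation's set contains the viable offspring of every (unordered, self
#' included) pair drawn from the previous set plus the resident background.
#' Only support matters — a gamete or karyomorph counts as reachable when
#' its probability is positive.
#'
#' @inheritParams simulate_dispersal
#' @param generations number of generations (>= 1).
#' @return A tibble with columns `generation` and `karyomorph`, one row per
#'   reachable karyomorph per generation.
#' @examples
#' reachable_types("IV", "I", segregation_params(0.9, 0.1, 0), generations = 3)
#' @export
reachable_types <- function(migrant, resident,
                            params = segregation_params(),
                            viability = default_viability(),
                            generations = 1) {
  if (generations < 1) abort_model("generations must be >= 1")
  support_of <- function(a, b) {
    cross_karyomorphs(a, b, params, viability)$karyomorph
  }
  sets <- vector("list", generations)
  sets[[1]] <- sort_karyomorphs(support_of(migrant, resident))
  if (generations > 1) {
    for (g in 2:generations) {
      parents <- union(sets[[g - 1]], resident)
      offs <- character(0)
      for (i in seq_along(parents)) {
        for (j in i:length(parents)) {
          offs <- union(offs, support_of(parents[i], parents[j]))
        }
      }
      sets[[g]] <- sort_karyomorphs(offs)
    }
  }
  bind_rows(purrr::imap(sets, function(s, g) {
    tibble(generation = as.integer(g), karyomorph = s)
  }))
}

sort_karyomorphs <- function(labels) {
  universe <- all_karyomorphs()
  known <- universe[universe %in% labels]
  c(known, sort(setdiff(labels, universe)))
}

#' Summarise a simulated trajectory
#'
#' Aggregates a long trajectory (as produced by [simulate_generations()] or
#' [simulate_dispersal()]) into one row per generation: one frequency column
#' per karyomorph plus the heteromorphic-carrier fraction (individuals with
#' at least one visibly unequal focal pair).
#'
#' @param trajectory a tibble with columns `generation`, `karyomorph`,
#'   `freq`.
#' @return A wide tibble, one row per generation, karyomorph frequency
#'   columns in canonical order, and a final `het_fraction` column.
#' @export
summarize_trajectory <- function(trajectory) {
  if (!all(c("generation", "karyomorph", "freq") %in% names(trajectory))) {
    abort_schema("trajectory needs columns generation, karyomorph, freq")
  }
  info <- karyomorph_table()
  het_labels <- info$karyomorph[info$heteromorphic]
  wide <- trajectory |>
    group_by(.data$generation) |>
    summarise(
      het_fraction = sum(.data$freq[.data$karyomorph %in% het_labels]) /
        sum(.data$freq),
      .groups = "drop"
    )
  freq_cols <- trajectory |>
    select("generation", "karyomorph", "freq") |>
    tidyr::pivot_wider(
      names_from = "karyomorph", values_from = "freq", values_fill = 0,
      values_fn = sum
    )
  ord <- sort_karyomorphs(setdiff(names(freq_cols), "generation"))
  freq_cols <- select(freq_cols, all_of(c("generation", ord)))
  left_join(freq_cols, wide, by = "generation") |>
    arrange(.data$generation)
}
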