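#' Segregation-mode probabilities for the quadrivalent
#'
#' A translocation heterozygote (type IV, MT/mSt) forms a quadrivalent at
#' meiosis I that can resolve by alternate, adjacent-1 or adjacent-2
#' segregation; the three mode probabilities must form a probability
#' simplex. The two gametes within a mode are assumed equiprobable.
#'
#' @param p_alt,p_adj1,p_adj2 mode probabilities, each >= 0, summing to 1.
#' @return An object of class `segregation_params`.
#' @examples
#' segregation_params(0.9, 0.1, 0)
#' @export
segregation_params <- function(p_alt = 1, p_adj1 = 0, p_adj2 = 0) {
  p <- c(alternate = p_alt, adjacent1 = p_adj1, adjacent2 = p_adj2)
  check_simplex(p, "segregation mode probabilities")
  structure(as.list(p), class = "segregation_params")
}

#' @export
print.segregation_params <- function(x, ...) {
  cat(sprintf(
    "Quadrivalent segregation modes: alternate %.4g, adjacent-1 %.4g, adjacent-2 %.4g\n",
    x$alternate, x$adjacent1, x$adjacent2
  ))
  invisible(x)
}

as_segregation_params <- function(x) {
  if (inherits(x, "segregation_params")) return(x)
  if (is.numeric(x) && length(x) == 3) {
    nm <- names(x) %||% c("p_alt", "p_adj1", "p_adj2")
    x <- as.list(setNames(unname(x), nm))
  }
  segregation_params(
    p_alt = x$p_alt %||% x$alternate %||% 0,
    p_adj1 = x$p_adj1 %||% x$adjacent1 %||% 0,
    p_adj2 = x$p_adj2 %||% x$adjacent2 %||% 0
  )
}

# canonical gamete label: two codes sorted M < m < T < St, joined by "/",
# reproducing the field notation (M/m, T/St, M/St, m/T, M/T, m/St)
gamete_label <- function(codes) {
  .check_codes(codes)
  paste(sort_codes(codes), collapse = "/")
}

gamete_codes <- function(label) {
  codes <- strsplit(label, "/", fixed = TRUE)[[1]]
  if (length(codes) != 2) {
    abort_model(sprintf("cannot parse gamete label '%s'", label))
  }
  .check_codes(codes)
  sort_codes(codes)
}

# a gamete is genetically balanced iff it carries a complete genic
# complement: one chromosome-1 centromere member and one chromosome-6
# member, both normal or both translocated
BALANCED_GAMETES <- c("M/m", "T/St")

#' The gametes of a translocation heterozygote
#'
#' The six gamete classes the type IV quadrivalent can produce, by
#' segregation mode: `M/m` and `T/St` (alternate, balanced), `M/St` and
#' `m/T` (adjacent-1), `M/T` and `m/St` (adjacent-2).
#'
#' @param modes which segregation modes to include; any subset of
#'   `c("alternate", "adjacent1", "adjacent2")` (abbreviations `alt`,
#'   `adj1`, `adj2` are accepted).
#' @return Character vector of gamete labels.
#' @examples
#' heterozygote_gametes() # all six
#' heterozygote_gametes(c("alt", "adj1")) # the four observed in the survey
#' @export
heterozygote_gametes <- function(modes = c("alternate", "adjacent1", "adjacent2")) {
  lut <- c(
    alt = "alternate", adj1 = "adjacent1", adj2 = "adjacent2",
    alternate = "alternate", adjacent1 = "adjacent1", adjacent2 = "adjacent2"
  )
  modes <- unname(lut[modes])
  if (any(is.na(modes))) abort_model("unknown segregation mode name")
  by_mode <- list(
    alternate = c("M/m", "T/St"),
    adjacent1 = c("M/St", "m/T"),
    adjacent2 = c("M/T", "m/St")
  )
  unlist(by_mode[unique(modes)], use.names = FALSE)
}

#' Gamete distribution of a karyomorph
#'
#' Returns the probability distribution over gamete classes produced by a
#' genotype. The translocation heterozygote (type IV) segregates through the
#' quadrivalent: each mode's two gametes get half the mode probability.
#' Focal homozygotes (I, IX, VI, VII) produce a single gamete class. Other
#' balanced genotypes have only one heteromorphic slot, so no quadrivalent
#' forms and the slots segregate as independent bivalents (one chromosome
#' per slot, uniform). Unbalanced multisets segregate as a uniform random
#' bipartition of their four chromosomes.
#'
#' @param karyomorph a karyomorph label (see [karyomorph_label()]).
#' @param params a [segregation_params()] object (or coercible list); only
#'   used for type IV.
#' @return A tibble with columns `gamete`, `mode`, `prob` (rows with zero
#'   probability are dropped).
#' @examples
#' gamete_distribution("IV", segregation_params(1, 0, 0))
#' gamete_distribution("II")
#' @export
gamete_distribution <- function(karyomorph, params = segregation_params()) {
  params <- as_segregation_params(params)
  codes <- codes_from_label(karyomorph)
  label <- karyomorph_label(codes)
  chr1 <- codes[codes %in% CHR1_CODES]
  chr6 <- codes[codes %in% CHR6_CODES]

  if (label == "IV") {
    out <- tibble(
      gamete = heterozygote_gametes(),
      mode = rep(c("alternate", "adjacent1", "adjacent2"), each = 2),
      prob = rep(c(params$alternate, params$adjacent1, params$adjacent2) / 2, each = 2)
    )
  } else if (length(chr1) == 2) {
    # balanced, at most one heteromorphic slot: independent bivalents
    combos <- expand.grid(a = chr1, b = chr6, stringsAsFactors = FALSE)
    out <- tibble(
      gamete = vapply(seq_len(nrow(combos)), function(i) {
        gamete_label(c(combos$a[i], combos$b[i]))
      }, character(1)),
      mode = "trivial",
      prob = 1 / nrow(combos)
    )
  } else {
    # unbalanced multiset: uniform random bipartition into two dyads
    pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
    gam <- unlist(lapply(pairings, function(p) {
      c(
        gamete_label(codes[p[1:2]]),
        gamete_label(codes[p[3:4]])
      )
    }))
    out <- tibble(gamete = gam, mode = "trivial", prob = 1 / 6)
  }

  out <- out |>
    group_by(.data$gamete, .data$mode) |>
    summarise(prob = sum(.data$prob), .groups = "drop") |>
    filter(.data$prob > 0) |>
    arrange(dplyr::desc(.data$prob), .data$gamete)
  out
}

#' Default viability map
#'
#' Per-karyomorph zygote viability. The default encodes the survey's
#' observation: only types I-V occur; types VI-IX and every unbalanced
#' multiset are lethal.
#'
#' @return Named numeric vector over the 19 enumerable karyomorphs with
#'   values in \[0, 1\].
#' @examples
#' default_viability()
#' @export
default_viability <- function() {
  labels <- all_karyomorphs()
  v <- setNames(rep(0, length(labels)), labels)
  v[c("I", "II", "III", "IV", "V")] <- 1
  v
}

#' Construct a viability map
#'
#' Starts from a baseline (by default [default_viability()]) and overrides
#' individual karyomorph viabilities.
#'
#' @param ... named viability overrides, e.g. `IX = 1`.
#' @param .default baseline value for every karyomorph not otherwise named;
#'   if `NULL`, the baseline is [default_viability()].
#' @return Named numeric vector over the 19 enumerable karyomorphs.
#' @examples
#' viability_map(IX = 1) # let translocation homozygotes live
#' viability_map(.default = 1) # all viable
#' @export
viability_map <- function(..., .default = NULL) {
  v <- if (is.null(.default)) {
    default_viability()
  } else {
    setNames(rep(.default, length(all_karyomorphs())), all_karyomorphs())
  }
  over <- c(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), all_karyomorphs())
    if (length(bad) > 0) {
      abort_model(sprintf("unknown karyomorph label(s) in viability map: %s",
                          paste(bad, collapse = ", ")))
    }
    if (any(over < 0 | over > 1)) abort_model("viabilities must lie in [0, 1]")
    v[names(over)] <- over
  }
  v
}

# viability lookup with 0 for labels outside the map
viability_of <- function(viability, labels) {
  out <- unname(viability[labels])
  out[is.na(out)] <- 0
  out
}

#' Enumerate offspring karyomorphs from a gamete set
#'
#' Forms every unordered pair of gametes (including self-pairs) and collects
#' the distinct four-chromosome multisets. Karyologically identical multisets
#' arising from different gamete pairs collapse to one karyomorph: `M/m +
#' T/St`, `M/St + m/T` and `M/T + m/St` all yield type IV.
#'
#' @param gametes character vector of gamete labels (e.g.
#'   `heterozygote_gametes()`), or a data frame with a `gamete` column.
#' @return A tibble with columns `karyomorph` and `balanced`, one row per
#'   distinct offspring karyomorph.
#' @examples
#' nrow(enumerate_offspring(heterozygote_gametes())) # 19
#' nrow(enumerate_offspring(heterozygote_gametes(c("alt", "adj1")))) # 9
#' @export
enumerate_offspring <- function(gametes) {
  if (is.data.frame(gametes)) gametes <- gametes$gamete
  gametes <- unique(gametes)
  if (length(gametes) == 0) abort_model("gamete set must be non-empty")
  code_pairs <- lapply(gametes, gamete_codes)
  labs <- character(0)
  for (i in seq_along(code_pairs)) {
    for (j in i:length(code_pairs)) {
      labs <- c(labs, karyomorph_label(c(code_pairs[[i]], code_pairs[[j]])))
    }
  }
  labs <- unique(labs)
  roman <- ROMAN_LABELS[ROMAN_LABELS %in% labs]
  labs <- c(roman, sort(setdiff(labs, roman)))
  tibble(
    karyomorph = labs,
    balanced = vapply(labs, is_balanced_label, logical(1), USE.NAMES = FALSE)
  )
}

#' Offspring distribution of a cross
#'
#' Convolves the two parents' gamete distributions, maps every gamete pair
#' to its offspring karyomorph, applies viability selection and (by default)
#' renormalises over the surviving mass — i.e. frequencies among the living.
#'
#' @param a,b parental karyomorph labels.
#' @param params segregation-mode probabilities, see [segregation_params()].
#' @param viability named viability vector, see [viability_map()].
#' @param normalize if `TRUE` (default) renormalise to frequencies among
#'   surviving offspring; if `FALSE` return viability-weighted zygote
#'   probabilities summing to the surviving mass.
#' @return A tibble with columns `karyomorph` and `prob`. Attribute
#'   `surviving_mass` carries the pre-normalisation surviving fraction. When
#'   every offspring is inviable the result has zero rows and attribute
#'   `sterile = TRUE` — a signal, not an error.
#' @examples
#' cross_karyomorphs("IV", "I", segregation_params(0.9, 0.1, 0))
#' @export
cross_karyomorphs <- function(a, b, params = segregation_params(),
                              viability = default_viability(),
                              normalize = TRUE) {
  params <- as_segregation_params(params)
  ga <- gamete_distribution(a, params)
  gb <- gamete_distribution(b, params)
  grid <- tidyr::expand_grid(i = seq_len(nrow(ga)), j = seq_len(nrow(gb)))
  labs <- vapply(seq_len(nrow(grid)), function(k) {
    karyomorph_label(c(
      gamete_codes(ga$gamete[grid$i[k]]),
      gamete_codes(gb$gamete[grid$j[k]])
    ))
  }, character(1))
  zyg <- tibble(karyomorph = labs, prob = ga$prob[grid$i] * gb$prob[grid$j]) |>
    group_by(.data$karyomorph) |>
    summarise(prob = sum(.data$prob), .groups = "drop")

  v <- viability_of(viability, zyg$karyomorph)
  zyg$prob <- zyg$prob * v
  mass <- sum(zyg$prob)
  zyg <- filter(zyg, .data$prob > 0)

  if (normalize) {
    if (mass < 1e-12) {
      out <- tibble(karyomorph = character(0), prob = numeric(0))
      attr(out, "sterile") <- TRUE
      attr(out, "surviving_mass") <- 0
      return(out)
    }
    zyg$prob <- zyg$prob / mass
  }
  out <- arrange(zyg, match(.data$karyomorph, all_karyomorphs()))
  attr(out, "sterile") <- FALSE
  attr(out, "surviving_mass") <- mass
  out
}
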