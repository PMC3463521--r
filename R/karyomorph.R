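#' @title Focal chromosome codes and karyomorph labels
#' @description
#' The polymorphism involves the four members of the translocation
#' quadrivalent: the large metacentric no. 1 homolog (`M`), its translocated
#' large telocentric counterpart (`T`), the small metacentric no. 6 homolog
#' (`m`), and its translocated large subtelocentric counterpart (`St`). A
#' karyomorph is the multiset of four focal chromosomes an individual
#' carries. Balanced karyomorphs (exactly two chromosomes per homolog slot)
#' take the Roman labels I-IX; all other multisets get a systematic label,
#' the four codes sorted in the order `M < m < T < St` and concatenated
#' (e.g. `"MMmT"`).
#' @name karyomorph-codes
NULL

# code alphabet and canonical ordering; 5S rDNA marks the chromosome-1
# derived members (M and its translocated derivative T)
FOCAL_CODES <- c("M", "m", "T", "St")
.code_rank <- c(M = 1, m = 2, T = 3, St = 4)
CHR1_CODES <- c("M", "T")
CHR6_CODES <- c("m", "St")

ROMAN_LABELS <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX")

# Roman label <-> constitution ("chr1 pair / chr6 pair") grid
.roman_constitution <- c(
  I = "MM/mm", II = "MM/mSt", III = "MT/mm", IV = "MT/mSt", V = "MT/StSt",
  VI = "MM/StSt", VII = "TT/mm", VIII = "TT/mSt", IX = "TT/StSt"
)
.constitution_roman <- setNames(names(.roman_constitution), .roman_constitution)

sort_codes <- function(codes) codes[order(.code_rank[codes])]

.check_codes <- function(codes) {
  bad <- setdiff(unique(codes), FOCAL_CODES)
  if (length(bad) > 0) {
    abort_model(sprintf(
      "unknown focal chromosome code(s): %s (alphabet is M, m, T, St)",
      paste(bad, collapse = ", ")
    ))
  }
  invisible(codes)
}

#' Canonical karyomorph label for a four-chromosome multiset
#'
#' @param codes character vector of exactly four focal codes (`M`, `m`, `T`,
#'   `St`), in any order.
#' @return A single label: a Roman numeral `I`-`IX` when the multiset is
#'   balanced (two chromosome-1 members, two chromosome-6 members), otherwise
#'   the systematic sorted-code string.
#' @examples
#' karyomorph_label(c("T", "m", "St", "M")) # "IV"
#' karyomorph_label(c("M", "M", "m", "T")) # unbalanced: "MMmT"
#' @export
karyomorph_label <- function(codes) {
  if (length(codes) != 4) {
    abort_model("a karyomorph is a multiset of exactly 4 focal chromosomes")
  }
  .check_codes(codes)
  chr1 <- sort_codes(codes[codes %in% CHR1_CODES])
  chr6 <- sort_codes(codes[codes %in% CHR6_CODES])
  if (length(chr1) == 2 && length(chr6) == 2) {
    constitution <- paste0(
      paste(chr1, collapse = ""), "/", paste(chr6, collapse = "")
    )
    unname(.constitution_roman[[constitution]])
  } else {
    paste(sort_codes(codes), collapse = "")
  }
}

#' Build a karyomorph label from the two homolog pairs
#'
#' Order within a pair is irrelevant; `(T, M)/(St, m)` and `(M, T)/(m, St)`
#' both canonicalise to type IV.
#'
#' @param chr1_pair,chr6_pair character vectors of two focal codes each.
#' @return The canonical karyomorph label.
#' @examples
#' karyomorph_from_codes(c("M", "M"), c("m", "m")) # "I"
#' karyomorph_from_codes(c("T", "M"), c("St", "m")) # "IV"
#' @export
karyomorph_from_codes <- function(chr1_pair, chr6_pair) {
  if (length(chr1_pair) != 2 || length(chr6_pair) != 2) {
    abort_model("each homolog slot must contain exactly two chromosomes")
  }
  karyomorph_label(c(chr1_pair, chr6_pair))
}

#' Recover the code multiset from a karyomorph label
#'
#' Accepts a Roman numeral (`"IV"`), a constitution string (`"MT/mSt"`), or a
#' systematic sorted-code string (`"MMmT"`).
#'
#' @param label a single karyomorph label.
#' @return Character vector of four focal codes in canonical order.
#' @export
codes_from_label <- function(label) {
  stopifnot(length(label) == 1)
  if (label %in% ROMAN_LABELS) label <- .roman_constitution[[label]]
  stripped <- gsub("/", "", label, fixed = TRUE)
  codes <- regmatches(stripped, gregexpr("St|M|m|T", stripped))[[1]]
  if (length(codes) != 4 || sum(nchar(codes)) != nchar(stripped)) {
    abort_model(sprintf("cannot parse karyomorph label '%s'", label))
  }
  .check_codes(codes)
  sort_codes(codes)
}

# label whose multiset is balanced (two members per slot)
is_balanced_label <- function(label) {
  codes <- codes_from_label(label)
  sum(codes %in% CHR1_CODES) == 2
}

#' The enumerable karyomorph universe
#'
#' All 19 karyologically distinct four-chromosome multisets that unordered
#' pairings of the six heterozygote gametes can produce, with their
#' constitution, balance status, heteromorphism and translocated-chromosome
#' dose, and the default viability (types I-V viable, everything else
#' lethal, as observed in the field survey).
#'
#' @return A tibble with one row per karyomorph: `karyomorph`,
#'   `constitution`, `balanced`, `heteromorphic`, `n_translocated`,
#'   `viable_default`.
#' @examples
#' karyomorph_table()
#' @export
karyomorph_table <- function() {
  labels <- all_karyomorphs()
  info <- purrr::map(labels, function(lab) {
    codes <- codes_from_label(lab)
    chr1 <- codes[codes %in% CHR1_CODES]
    chr6 <- codes[codes %in% CHR6_CODES]
    balanced <- length(chr1) == 2
    tibble(
      karyomorph = lab,
      constitution = if (balanced) {
        paste0(paste(chr1, collapse = ""), "/", paste(chr6, collapse = ""))
      } else {
        NA_character_
      },
      balanced = balanced,
      # a heteromorphic karyotype shows at least one visibly unequal pair;
      # unbalanced multisets cannot pair evenly and count as heteromorphic
      heteromorphic = if (balanced) {
        chr1[1] != chr1[2] || chr6[1] != chr6[2]
      } else {
        TRUE
      },
      n_translocated = sum(codes %in% c("T", "St"))
    )
  })
  out <- bind_rows(info)
  out$viable_default <- unname(default_viability()[out$karyomorph])
  out
}

# the 19 labels, Roman types first, then systematic strings (memoised:
# computed once per session by enumerating the six-gamete pairings)
.pkg_cache <- new.env(parent = emptyenv())
all_karyomorphs <- function() {
  if (is.null(.pkg_cache$all19)) {
    .pkg_cache$all19 <- enumerate_offspring(heterozygote_gametes())$karyomorph
  }
  .pkg_cache$all19
}

#' Classify centromere position from the arm ratio
#'
#' Levan-style classification of the centromere position from the arm ratio
#' r (long arm / short arm), using the conventional cut points: metacentric
#' for r in \[1, 1.7), submetacentric \[1.7, 3), subtelocentric \[3, 7),
#' telocentric \[7, Inf). Intervals are half-open with the lower bound
#' included.
#'
#' @param arm_ratio numeric vector of arm ratios, each >= 1.
#' @return An ordered factor with levels `metacentric < submetacentric <
#'   subtelocentric < telocentric`.
#' @examples
#' classify_centromere(c(1.23, 3.35, 7.11))
#' @export
classify_centromere <- function(arm_ratio) {
  if (any(!is.finite(arm_ratio)) || any(arm_ratio < 1)) {
    abort_schema("arm_ratio must be finite and >= 1 (long arm / short arm)")
  }
  cut(
    arm_ratio,
    breaks = c(1, 1.7, 3, 7, Inf),
    labels = c("metacentric", "submetacentric", "subtelocentric", "telocentric"),
    right = FALSE, include.lowest = TRUE, ordered_result = TRUE
  )
}

#' Classify chromosome size from relative length
#'
#' The survey's large/small dichotomy, thresholded on relative length
#' (percent of the complement). The default cutoff of 7 percent separates
#' the largest small chromosome from the smallest large one in both printed
#' idiograms.
#'
#' @param relative_length numeric vector of relative lengths (percent), > 0.
#' @param cutoff size threshold in percent; `large` iff
#'   `relative_length >= cutoff`.
#' @return A factor with levels `small`, `large`.
#' @export
classify_size <- function(relative_length, cutoff = 7) {
  if (any(!is.finite(relative_length)) || any(relative_length <= 0)) {
    abort_schema("relative_length must be finite and > 0")
  }
  factor(
    ifelse(relative_length >= cutoff, "large", "small"),
    levels = c("small", "large")
  )
}

#' Compact Levan code for a classified chromosome
#'
#' Combines centromere class and size class into the survey's shorthand:
#' `M`/`m` (meta), `Sm`/`sm` (submeta), `St`/`st` (subtelo), `T`/`t` (telo),
#' upper case for large chromosomes.
#'
#' @param centromere_class factor or character as returned by
#'   [classify_centromere()].
#' @param size_class factor or character as returned by [classify_size()].
#' @return Character vector of codes.
#' @export
levan_code <- function(centromere_class, size_class) {
  base <- c(
    metacentric = "m", submetacentric = "sm",
    subtelocentric = "st", telocentric = "t"
  )[as.character(centromere_class)]
  large <- as.character(size_class) == "large"
  out <- base
  out[large] <- vapply(base[large], function(x) {
    paste0(toupper(substr(x, 1, 1)), substring(x, 2))
  }, character(1))
  unname(out)
}
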