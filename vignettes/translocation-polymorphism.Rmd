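---
title: "Modelling a reciprocal-translocation polymorphism from karyomorph data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a reciprocal-translocation polymorphism from karyomorph data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadrivalent)
library(dplyr)
```

## The system

The Asian spiny frog *Quasipaa boulengeri* (2n = 26) carries a reciprocal
translocation between chromosomes 1 and 6: nearly the whole short arm of the
large metacentric chromosome 1 has been exchanged with a small segment of the
small metacentric chromosome 6, producing a large telocentric derivative (`T`)
and a large subtelocentric derivative (`St`). An individual's *karyomorph* is
the multiset of the four focal chromosomes it carries, written as the
chromosome-1 pair over the chromosome-6 pair. Nine balanced combinations exist
(types I–IX, from the normal `MM/mm` to the translocation homozygote
`TT/StSt`), but field surveys find only five (I–V): the translocation
heterozygote `MT/mSt` (type IV) is common in some populations while types
VI–IX are absent everywhere.

This package implements the quantitative machinery needed to analyse that
polymorphism: morphometric karyotype classification, the quadrivalent
segregation model and its offspring algebra, viability-filtered forward
simulation of the dispersal scenario, and maximum-likelihood inference of
gamete-pool frequencies from count tables. A seeded synthetic-data module
generates every input format the pipeline consumes, so the whole analysis is
testable without any external data.

## Karyotype classification

Chromosomes are described by two morphometric quantities: the **relative
length** (RL, one chromosome's length as a percent of the complement total)
and the **arm ratio** (AR, long arm over short arm, always ≥ 1). The
centromere position follows the conventional Levan-style cut points on AR,
half-open with the lower bound included:

| class | AR interval |
|---|---|
| metacentric | [1.0, 1.7) |
| submetacentric | [1.7, 3.0) |
| subtelocentric | [3.0, 7.0) |
| telocentric | [7.0, ∞) |

The large/small dichotomy is thresholded on RL at 7 percent (configurable).
The cutoff separates the largest small chromosome (RL 6.09 in the normal
idiogram) from the smallest large one (RL 8.19 in the heterozygote idiogram)
with a comfortable margin in both packaged idiograms.

Two conventions deserve note:

* **Relative-length scale.** Published idiogram tables normalise RL per
  *distinct-morphology set*: each homomorphic pair appears once, while the
  four heteromorphic focal chromosomes of a type IV cell are listed singly,
  and the printed values sum to ~100 on that scale. The package keeps the
  printed scale. The per-cell plausibility check therefore recomputes the
  distinct-set total (homomorphic pairs counted once by their mean, focal
  heteromorphic homologs singly) and warns when it deviates from 100 by more
  than ±5. Five percentage points is ~6 standard deviations of that total
  under the packaged per-chromosome noise levels, so the check flags gross
  transcription errors without tripping on ordinary measurement noise.

* **Focal code assignment.** The 5S rDNA locus sits near the centromere of
  both chromosome-1 homologs in every karyomorph, so chromosomes flagged with
  a 5S signal are forced into the chromosome-1 slot; without flags the
  measurement table's pair numbering is used. Within a slot, codes are
  assigned by a coarse centromere rule — metacentric means the normal member
  (`M`/`m`); a clearly acentric chromosome (AR ≥ 3) in the chromosome-1 slot
  is the translocated `T`; any non-metacentric chromosome in the
  chromosome-6 slot is the translocated `St` — rather than by the exact
  Levan partition. The reason is numerical: the printed mean arm ratios of
  the derived chromosomes sit almost on Levan boundaries (`T`: 7.11 ± 0.11
  against the 7.0 telocentric cut; `St`: 3.35 ± 0.31 against the 3.0
  subtelocentric cut), so a hard-boundary rule would mistype 13–16 % of
  cells at realistic noise, whereas the normal members are 4–5 SDs inside
  the metacentric interval. A chromosome-1 homolog falling in the
  submetacentric band is genuinely ambiguous and raises an error naming the
  offending measurement. The full per-chromosome Levan classes are still
  computed with the exact boundaries and reported alongside.

```{r classify}
cells <- read_measurements(example_path("idiogram_measurements.csv"))
classify_karyotype(cells) |> select(-chromosomes)
```

## The quadrivalent segregation model

At meiosis the type IV heterozygote forms a quadrivalent of `M`, `T`, `m`,
`St` that resolves by one of three modes, each producing two gamete classes
assumed equiprobable within the mode:

* **alternate** — `M/m` and `T/St`, both genetically balanced;
* **adjacent-1** — `M/St` and `m/T`, unbalanced (non-homologous centromeres
  separate);
* **adjacent-2** — `M/T` and `m/St`, unbalanced (homologous centromeres
  co-migrate).

Unordered pairings (self-pairings included) of all six gametes yield **19**
karyologically distinct offspring multisets; restricting to the four
alternate + adjacent-1 gametes yields exactly the nine balanced types I–IX.
Multisets from different gamete pairs that coincide karyologically are
merged — `M/m + T/St`, `M/St + m/T` and `M/T + m/St` are all type IV — which
is what "karyologically distinct" means here; the genetic imbalance of
adjacent-2 derived type IV zygotes is expressed through viability, not
through the label.

```{r enumerate}
enumerate_offspring(heterozygote_gametes()) |> nrow()
enumerate_offspring(heterozygote_gametes(c("alt", "adj1")))$karyomorph
```

Genotypes other than type IV have at most one heteromorphic focal pair, so no
quadrivalent forms: their slots segregate as independent bivalents, one
chromosome per slot with equal probability (type II gives `M/m` and `M/St` at
1/2 each; focal homozygotes give a single gamete class). For the unbalanced
multisets — which never breed under the default viability but must still have
a defined distribution — the four chromosomes are bipartitioned uniformly at
random into two dyads. These two rules are the package's own completion of
the model; only the type IV quadrivalent is prescribed by the biology.

**Viability.** The default viability map encodes the survey's central
observation: types I–V viable, types VI–IX and every unbalanced multiset
lethal. Crosses convolve the parental gamete distributions, apply viability,
and by default renormalise over the surviving mass (frequencies among living
frogs — fecundity compensation); an unnormalised mode reports the surviving
mass itself. A cross whose offspring are all inviable returns an empty
distribution flagged sterile rather than an error. Simplex-type inputs are
validated to 1e−9.

## Forward simulation and the dispersal scenario

`step_population()` is the deterministic recursion: random union of the
population gamete pool, viability filtering, renormalisation. The finite-N
mode draws each next generation multinomially from the deterministic
distribution under an explicit integer seed (mandatory; the global RNG state
is never touched). Mating is random with non-overlapping generations, and
karyomorphs are treated as autosomal: sexes contribute symmetrically, so the
state space is frequencies over karyomorphs.

The dispersal scenario — one type IV migrant entering a type I population —
needs one refinement: a single migrant cannot mate with itself. A pure
pool-union first generation would put O(1/N²) mass on migrant-selfing and
thus produce type V (which requires *two* heterozygote parents) a generation
early. `simulate_dispersal()` therefore builds the first generation from
migrant-by-resident matings (a fraction 1/N of all pairs, the migrant
entering at frequency 1/(2N)) and resident-by-resident matings, and only from
the second generation on uses the panmictic pool recursion. With adjacent-2
segregation absent, the F1 support is exactly {I, II, III, IV}, and from F2
onward the support stabilises at the five observed types — type V appears
once two heterozygotes can meet. `reachable_types()` runs the same logic as a
set-valued recursion (supports only, no magnitudes).

```{r dispersal}
reachable_types("IV", "I", segregation_params(0.9, 0.1, 0), generations = 3)
```

## Inference

**Frequency tables.** `frequency_table()` pools sexes within populations,
keeps exact proportions internally, and prints percentages rounded half-up to
one decimal, matching the published style. Empty populations are flagged
rather than dropped.

**Gamete-pool likelihood.** The observed karyomorph counts are modelled as a
multinomial over the viable types, whose pre-selection zygote frequencies
come from random union of the four occurring gametes with frequencies
f₁ (`M/m`), f₂ (`T/St`), f₃ (`M/St`), f₄ (`m/T`):

I: f₁², II: 2f₁f₃, III: 2f₁f₄, IV: 2f₁f₂ + 2f₃f₄, V: 2f₂f₃, VI: f₃²,
VII: f₄², VIII: 2f₂f₄, IX: f₂²,

restricted and renormalised to the viable set. The type IV cell has two
terms because both the alternate-complementary union and the double
adjacent-1 union are karyologically `MT/mSt`. The likelihood (in frequency
form, Σ n log p, hence always ≤ 0) is maximised over the 3-simplex by
Nelder–Mead in a softmax parameterisation from a deterministic 27-point start
grid; convergence and boundary optima are reported as flags, never hidden.
The survey counts give a pool dominated by alternate-mode gametes
(f̂₁ ≈ 0.90, f̂₂ ≈ 0.09), quantifying the argument that alternate segregation
predominates. The test suite cross-checks the optimiser against a dense grid
search over the simplex (step 0.005) and verifies parameter recovery on
synthetic counts.

```{r fit}
fit <- fit_gamete_pool(example_karyomorph_counts())
tidy(fit)
glance(fit)
```

**Arm-length conservation.** A reciprocal exchange moves chromatin but does
not create or destroy it, so per cell the summed length of the four
heteromorphic chromosomes should match twice the summed length of the two
normal homologs. `arm_conservation_test()` computes both sums per cell and a
paired two-sided t-test across cells; on the packaged ten-cell table the
means are 17.72 and 18.07 μm with p ≈ 0.06, consistent with conservation.

```{r arm}
arm_conservation_test(example_length_table())
```

## Synthetic data

The generators emulate the statistical structure the analysis assumes, with
every draw governed by a mandatory integer seed (inverse-CDF truncated
normals, so output is identical regardless of rejection behaviour):

* `generate_cells()` draws per-chromosome RL and AR from lower-truncated
  normals at the idiogram moments (RL > 0, AR ≥ 1), rescales each cell's RLs
  to the idiogram total, and sets 5S flags on the chromosome-1 homologs. The
  packaged moments are the printed idiogram tables for types I and IV.
* `generate_counts()` draws population count tables from the
  viability-filtered random-union distribution of a gamete pool, with sexes
  assigned independently at 1:1 — the polymorphism is autosomal, so sex
  carries no information and is included only to exercise the table schema.
* `generate_lengths()` draws the four focal lengths per cell as base lengths
  times a lognormal per-cell scale factor (SD 0.25 on the log scale; measured
  metaphase cells vary about two-fold in total length) plus additive noise
  (SD 0.15 μm). The default base lengths (6.5, 4.2, 2.5, 4.8 μm, near the
  measured means) satisfy exact conservation, so the generator samples from
  the conservation test's null.

What the generators deliberately do *not* emulate: correlated measurement
error within a cell beyond the common scale factor, chromosome-bending and
spread artefacts, scoring drift between observers, or inter-population
structure in the gamete pool. Passing round-trip and recovery tests on this
synthetic data therefore demonstrates internal consistency of the methods,
not robustness to every failure mode of real cytogenetic material.

## Numerical choices and problem sizes

* Simplex tolerance 1e−9 for all probability inputs; renormalisation after
  viability filtering is the default everywhere.
* Half-up rounding for printed percentages (base R's `round()` is
  half-to-even, which would print 0.65 as 0.6).
* The likelihood optimiser restarts from 27 deterministic softmax points;
  the reported optimum is the best of all restarts, with boundary estimates
  (< 1e−5) flagged.
* Test problem sizes were chosen to exercise the asymptotics while keeping
  the suite quick: 1000 cells for the classification round trip, n = 5000
  individuals for parameter recovery, n up to 20 000 over five seeds for the
  consistency check, grid step 0.005 for the likelihood oracle, and 10⁵
  individuals for the convergence of generated marginals.

## Known limitations

* Chiasma formation and recombination within the quadrivalent, and the
  chain-versus-ring geometry of the multivalent, are abstracted into the
  three mode probabilities.
* Per-population fits are possible but most surveyed populations are
  monomorphic, so their estimates sit on the simplex boundary; the package
  reports the boundary flag rather than suppressing such fits.
* The dispersal scenario is reproduced qualitatively (which karyomorph sets
  can appear when), not fitted to per-population frequencies — the survey
  contains no temporal data to fit against.
* Confidence intervals for the gamete-pool estimates are not computed;
  the likelihood surface is available through the exported machinery should
  profile intervals be needed.
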