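# forward simulation and reachability

test_that("a monomorphic normal population is a fixed point", {
  nxt <- step_population(c(I = 1))
  expect_equal(nxt, c(I = 1), ignore_attr = TRUE)
  traj <- simulate_generations(c(I = 1), generations = 5)
  expect_true(all(traj$karyomorph == "I"))
  expect_true(all(traj$freq == 1))
})

test_that("the deterministic step agrees with the genotype-pair double sum", {
  withr::with_seed(31, {
    for (i in 1:5) {
      x <- runif(5)
      freqs <- setNames(x / sum(x), c("I", "II", "III", "IV", "V"))
      w <- runif(3)
      params <- segregation_params(w[1] / sum(w), w[2] / sum(w), w[3] / sum(w))
      for (viability in list(default_viability(), viability_map(.default = 1))) {
        got <- step_population(freqs, params, viability)
        want <- oracle_next_generation(as.list(freqs), params, viability)
        want <- want[order(match(names(want), names(got)))]
        expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
      }
    }
  })
})

test_that("without selection, alternate-only segregation conserves the translocated dose", {
  freqs <- c(I = 0.5, IV = 0.3, IX = 0.2)
  params <- segregation_params(1, 0, 0)
  all_viable <- viability_map(.default = 1)
  dose <- function(f) {
    info <- karyomorph_table()
    sum(f * info$n_translocated[match(names(f), info$karyomorph)] / 4)
  }
  d0 <- dose(freqs)
  traj <- simulate_generations(freqs, generations = 6, params = params,
                               viability = all_viable)
  for (g in unique(traj$generation)) {
    gen <- traj[traj$generation == g, ]
    expect_equal(dose(setNames(gen$freq, gen$karyomorph)), d0, tolerance = 1e-12)
  }
})

test_that("lethal karyomorphs never appear in any trajectory", {
  viable <- c("I", "II", "III", "IV", "V")
  withr::with_seed(59, {
    for (i in 1:5) {
      w <- runif(3)
      params <- segregation_params(w[1] / sum(w), w[2] / sum(w), w[3] / sum(w))
      det <- simulate_generations(c(I = 0.8, IV = 0.2), generations = 4,
                                  params = params)
      expect_true(all(det$karyomorph %in% viable))
      fin <- simulate_generations(c(I = 80, IV = 20), generations = 4,
                                  params = params, mode = "finite", seed = i)
      expect_true(all(fin$karyomorph %in% viable))
    }
  })
})

test_that("finite-population runs are reproducible from their seed", {
  a <- simulate_generations(c(I = 90, IV = 10), generations = 5,
                            params = segregation_params(0.8, 0.1, 0.1),
                            mode = "finite", seed = 77)
  b <- simulate_generations(c(I = 90, IV = 10), generations = 5,
                            params = segregation_params(0.8, 0.1, 0.1),
                            mode = "finite", seed = 77)
  expect_identical(a, b)
  expect_error(
    simulate_generations(c(I = 90, IV = 10), generations = 2, mode = "finite"),
    class = "quadrivalent_model_error"
  )
})

test_that("the migrant scenario delays type V to the second generation", {
  params <- segregation_params(0.9, 0.1, 0)
  traj <- simulate_dispersal(N = 50, generations = 3, params = params)
  wide <- summarize_trajectory(traj)
  expect_setequal(
    traj$karyomorph[traj$generation == 1],
    c("I", "II", "III", "IV")
  )
  expect_false("V" %in% traj$karyomorph[traj$generation == 1])
  expect_gt(wide$V[wide$generation == 2], 0)
  expect_setequal(
    traj$karyomorph[traj$generation == 2],
    c("I", "II", "III", "IV", "V")
  )
})

test_that("reachability reproduces the dispersal narrative", {
  params <- segregation_params(0.9, 0.1, 0)
  reach <- reachable_types("IV", "I", params, generations = 3)
  sets <- split(reach$karyomorph, reach$generation)
  expect_setequal(sets[["1"]], c("I", "II", "III", "IV"))
  expect_setequal(sets[["2"]], c("I", "II", "III", "IV", "V"))
  expect_setequal(sets[["3"]], c("I", "II", "III", "IV", "V"))
  # a resident population alone never innovates
  still <- reachable_types("I", "I", params, generations = 5)
  expect_true(all(still$karyomorph == "I"))
})

test_that("trajectory summaries carry per-generation frequencies and heterozygote fraction", {
  one <- summarize_trajectory(
    tibble::tibble(generation = 0L, karyomorph = "I", freq = 1)
  )
  expect_equal(nrow(one), 1)
  expect_equal(one$het_fraction, 0)

  traj <- simulate_generations(c(I = 0.7, IV = 0.3), generations = 4,
                               params = segregation_params(0.7, 0.3, 0))
  wide <- summarize_trajectory(traj)
  freq_cols <- setdiff(names(wide), c("generation", "het_fraction"))
  expect_equal(unname(rowSums(wide[freq_cols])), rep(1, nrow(wide)), tolerance = 1e-12)
  het <- traj |>
    dplyr::filter(karyomorph %in% c("II", "III", "IV", "V", "VIII")) |>
    dplyr::group_by(generation) |>
    dplyr::summarise(h = sum(freq))
  expect_equal(wide$het_fraction, het$h, tolerance = 1e-12)
})
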