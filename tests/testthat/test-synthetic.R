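# synthetic-data generators

test_that("generated cells reproduce the idiogram moments", {
  cells <- generate_cells("IV", n_cells = 1000, seed = 1)
  expect_equal(nrow(cells), 26000)
  st_ar <- cells$arm_ratio[cells$chrom_index == 6 & cells$homolog_id == 2]
  # 3 * SD / sqrt(n) band around the printed mean arm ratio of the St homolog
  expect_lt(abs(mean(st_ar) - 3.35), 0.05)
  expect_true(all(cells$arm_ratio >= 1))
  expect_true(all(cells$relative_length > 0))
  # 5S flags sit on the chromosome-1 homologs only
  expect_true(all(cells$has_5S_signal == (cells$chrom_index == 1)))
})

test_that("zero-noise generation returns the idiogram means exactly", {
  spec <- builtin_idiograms()
  spec$rl_sd <- 0
  spec$ar_sd <- 0
  cells <- generate_cells("I", n_cells = 3, idiogram = spec, seed = 9)
  means <- spec[spec$karyomorph == "I", ]
  for (cell in split(cells, cells$cell_id)) {
    expect_equal(cell$relative_length, means$rl_mean, tolerance = 1e-12)
    expect_equal(cell$arm_ratio, means$ar_mean, tolerance = 1e-12)
  }
})

test_that("generators are byte-deterministic given a seed", {
  expect_identical(
    generate_cells("IV", n_cells = 5, seed = 42),
    generate_cells("IV", n_cells = 5, seed = 42)
  )
  expect_identical(
    generate_counts(c(0.8, 0.1, 0.06, 0.04), pop_sizes = c(50, 50), seed = 3),
    generate_counts(c(0.8, 0.1, 0.06, 0.04), pop_sizes = c(50, 50), seed = 3)
  )
  expect_identical(
    generate_lengths(10, seed = 5),
    generate_lengths(10, seed = 5)
  )
  # and they do not disturb the global RNG state
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(generate_cells("I", n_cells = 1, seed = 99))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("a degenerate gamete pool yields only normal individuals", {
  counts <- generate_counts(c(1, 0, 0, 0), pop_sizes = c(200, 100), seed = 2)
  expect_true(all(counts$count[counts$karyomorph != "I"] == 0))
  expect_equal(sum(counts$count), 300)
  expect_equal(sort(unique(counts$population_id)), c("pop_01", "pop_02"))
})

test_that("default viability never produces the lethal karyomorphs", {
  counts <- generate_counts(c(0.5, 0.3, 0.1, 0.1), pop_sizes = rep(200, 5), seed = 13)
  dead <- counts$karyomorph %in% c("VI", "VII", "VIII", "IX")
  expect_true(all(counts$count[dead] == 0))
})

test_that("generated marginals converge to the analytic random-union distribution", {
  f <- c(0.8, 0.15, 0.03, 0.02)
  probs <- zygote_frequencies(f, default_viability())
  counts <- generate_counts(f, pop_sizes = 1e5, seed = 17)
  obs <- tapply(counts$count, counts$karyomorph, sum)[probs$karyomorph]
  tv <- sum(abs(obs / sum(obs) - probs$prob)) / 2
  expect_lt(tv, 0.02)
})

test_that("zero-noise lengths satisfy exact conservation and positive output", {
  lengths <- generate_lengths(5, noise_sd = 0, cell_scale_sd = 0, seed = 4)
  wide <- tidyr::pivot_wider(lengths, names_from = "chrom", values_from = "length_um")
  expect_equal(
    wide[["1-2"]] + wide[["6-2"]], wide[["1-1"]] + wide[["6-1"]],
    tolerance = 1e-12
  )
  noisy <- generate_lengths(50, seed = 6)
  expect_true(all(noisy$length_um > 0))
  expect_equal(nrow(noisy), 200)
})

test_that("the conservation test keeps its size under the generator's null", {
  p_over <- vapply(1:100, function(s) {
    arm_conservation_test(generate_lengths(10, seed = s))$p_value
  }, numeric(1))
  expect_gte(mean(p_over > 0.05), 0.9)
})

test_that("an idiogram missing chromosomes is a spec error", {
  spec <- builtin_idiograms()
  expect_error(
    generate_cells("IV", n_cells = 1, idiogram = spec[spec$chrom_index != 5, ], seed = 1),
    class = "quadrivalent_schema_error"
  )
  expect_error(
    generate_cells("II", n_cells = 1, seed = 1),
    class = "quadrivalent_model_error"
  )
})
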