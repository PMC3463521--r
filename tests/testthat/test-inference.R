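# frequency tables, gamete-pool likelihood, arm-length conservation

test_that("per-population frequencies sum to 100 percent", {
  ft <- frequency_table(example_karyomorph_counts())
  sums <- tapply(ft$percent, ft$population_id, sum)
  expect_true(all(abs(sums - 100) <= 0.1 + 1e-9))
  expect_false(any(ft$empty_population))
})

test_that("a single individual is 100 percent of its population", {
  one <- tibble::tibble(
    population_id = "p", sex = "female", karyomorph = "I", count = 1
  )
  ft <- frequency_table(one)
  expect_equal(ft$percent[ft$population_id == "p"], 100.0)
})

test_that("an empty population is flagged, not an error", {
  counts <- tibble::tibble(
    population_id = c("a", "b"), sex = "male",
    karyomorph = "I", count = c(3, 0)
  )
  ft <- frequency_table(counts, include_pooled = FALSE)
  expect_true(all(ft$empty_population[ft$population_id == "b"]))
  expect_true(all(is.na(ft$freq[ft$population_id == "b"])))
})

test_that("half-up rounding matches the printed style", {
  expect_equal(
    quadrivalent:::round_half_up(c(81.95, 16.135, 0.6369, 87.5), 1),
    c(82.0, 16.1, 0.6, 87.5)
  )
})

test_that("the zygote formulas agree with an explicit gamete-pair convolution", {
  gametes <- list(c("M", "m"), c("T", "St"), c("M", "St"), c("m", "T"))
  withr::with_seed(101, {
    for (rep in 1:5) {
      f <- runif(4)
      f <- f / sum(f)
      got <- zygote_frequencies(f)
      want <- numeric(0)
      for (i in 1:4) {
        for (j in 1:4) {
          lab <- karyomorph_label(c(gametes[[i]], gametes[[j]]))
          want[lab] <- (if (is.na(want[lab])) 0 else want[lab]) + f[i] * f[j]
        }
      }
      expect_equal(setNames(got$prob, got$karyomorph), want[got$karyomorph],
                   tolerance = 1e-12)
    }
  })
})

test_that("a monomorphic sample pins the pool on the normal gamete", {
  fit <- fit_gamete_pool(c(I = 250))
  expect_equal(unname(fit$estimates["M/m"]), 1, tolerance = 1e-6)
  expect_true(fit$boundary)
  expect_true(fit$converged)
})

test_that("the survey fit beats every grid point and preserves the observed ordering", {
  counts <- pooled_counts()
  fit <- fit_gamete_pool(example_karyomorph_counts())
  grid <- oracle_grid_loglik(counts, step = 0.01)
  expect_gte(fit$log_likelihood, grid$loglik - 1e-9)
  expect_lte(fit$log_likelihood, 0)
  expect_equal(sum(fit$expected), fit$n, tolerance = 1e-6)
  exp_counts <- fit$expected
  expect_true(exp_counts["I"] > exp_counts["IV"])
  expect_true(all(exp_counts["IV"] > exp_counts[c("II", "III", "V")]))
})

test_that("tidy and glance summarise the fit", {
  fit <- fit_gamete_pool(c(I = 380, II = 4, III = 2, IV = 80, V = 5))
  td <- tidy(fit)
  expect_equal(td$gamete, c("M/m", "T/St", "M/St", "m/T"))
  expect_equal(sum(td$estimate), 1, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n, 471)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("observed counts on inviable karyomorphs are rejected", {
  expect_error(
    fit_gamete_pool(c(I = 10, IX = 2)),
    class = "quadrivalent_model_error"
  )
})

test_that("estimator bias of the normal-gamete frequency vanishes with sample size", {
  f_true <- c(0.8, 0.15, 0.03, 0.02)
  mean_bias <- function(n) {
    est <- vapply(1:5, function(s) {
      counts <- generate_counts(f_true, pop_sizes = n, seed = 1000 + s)
      fit_gamete_pool(counts)$estimates[["M/m"]]
    }, numeric(1))
    abs(mean(est) - f_true[1])
  }
  biases <- vapply(c(200, 2000, 20000), mean_bias, numeric(1))
  expect_lt(biases[3], biases[1])
  expect_lt(biases[3], 0.005)
})

test_that("arm-length conservation reproduces the printed cell sums", {
  res <- arm_conservation_test(example_length_table())
  expect_equal(round(res$mean_het_sum, 2), 17.72)
  expect_equal(round(res$mean_norm_sum, 2), 18.07)
  expect_gt(res$p_value, 0.05)
  expect_equal(res$df, 9)
})

test_that("identical sums give a zero statistic and fewer than two cells error", {
  lengths <- tibble::tibble(
    cell_id = rep(1:3, each = 4),
    chrom = rep(c("1-1", "1-2", "6-1", "6-2"), 3),
    length_um = rep(c(6, 4, 2, 4), 3) # 1-2 + 6-2 == 1-1 + 6-1
  )
  res <- arm_conservation_test(lengths)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(
    arm_conservation_test(lengths[lengths$cell_id == 1, ]),
    class = "quadrivalent_model_error"
  )
})
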