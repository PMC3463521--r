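# quadrivalent segregation, gamete distributions, crosses

test_that("segregation parameters must form a simplex", {
  expect_error(segregation_params(0.5, 0.2, 0.2), class = "quadrivalent_model_error")
  expect_error(segregation_params(1.2, -0.2, 0), class = "quadrivalent_model_error")
  p <- segregation_params(0.9, 0.1, 0)
  expect_s3_class(p, "segregation_params")
  # within the stated tolerance, tiny float error is accepted
  expect_silent(segregation_params(1 / 3, 1 / 3, 1 / 3 + 1e-12))
})

test_that("the type IV quadrivalent yields each mode's gametes at half the mode weight", {
  g <- gamete_distribution("IV", segregation_params(1, 0, 0))
  expect_setequal(g$gamete, c("M/m", "T/St"))
  expect_equal(g$prob, c(0.5, 0.5))
  expect_true(all(g$mode == "alternate"))

  g3 <- gamete_distribution("IV", segregation_params(1 / 3, 1 / 3, 1 / 3))
  expect_setequal(g3$gamete, heterozygote_gametes())
  expect_equal(g3$prob, rep(1 / 6, 6), tolerance = 1e-12)
})

test_that("homozygous genotypes give a single trivial gamete", {
  for (lab in c("I", "IX", "VI", "VII")) {
    g <- gamete_distribution(lab)
    expect_equal(nrow(g), 1)
    expect_equal(g$prob, 1)
    expect_equal(g$mode, "trivial")
  }
  expect_equal(gamete_distribution("I")$gamete, "M/m")
  expect_equal(gamete_distribution("IX")$gamete, "T/St")
})

test_that("single-heteromorphic genotypes segregate as independent bivalents", {
  g2 <- gamete_distribution("II")
  expect_setequal(g2$gamete, c("M/m", "M/St"))
  expect_equal(g2$prob, c(0.5, 0.5))
  g5 <- gamete_distribution("V")
  expect_setequal(g5$gamete, c("M/St", "T/St"))
  # gamete probabilities always sum to one, also for unbalanced multisets
  for (lab in karyomorph_table()$karyomorph) {
    expect_equal(sum(gamete_distribution(lab)$prob), 1, tolerance = 1e-12)
  }
})

test_that("offspring enumeration matches brute force over every gamete subset", {
  six <- heterozygote_gametes()
  for (mask in 1:63) {
    keep <- which(bitwAnd(mask, 2^(0:5)) > 0)
    got <- nrow(enumerate_offspring(six[keep]))
    expect_equal(got, oracle_offspring_count(oracle_gametes[keep]))
  }
  expect_error(enumerate_offspring(character(0)), class = "quadrivalent_model_error")
  expect_equal(enumerate_offspring("M/m")$karyomorph, "I")
})

test_that("crosses reproduce the dispersal F1 and the alternate-only selfing", {
  f1 <- cross_karyomorphs("IV", "I", segregation_params(0.6, 0.4, 0))
  expect_setequal(f1$karyomorph, c("I", "II", "III", "IV"))
  expect_equal(sum(f1$prob), 1, tolerance = 1e-12)

  selfing <- cross_karyomorphs("IV", "IV", segregation_params(1, 0, 0),
                               viability = viability_map(.default = 1))
  expect_equal(
    setNames(selfing$prob, selfing$karyomorph),
    c(I = 0.25, IV = 0.5, IX = 0.25)
  )

  expect_equal(cross_karyomorphs("I", "I")$karyomorph, "I")
})

test_that("crosses are symmetric and conserve probability", {
  params_list <- list(
    segregation_params(1, 0, 0),
    segregation_params(0.5, 0.3, 0.2),
    segregation_params(0.2, 0.2, 0.6)
  )
  labs <- c("I", "II", "III", "IV", "V", "IX", "MMmT")
  withr::with_seed(11, {
    for (i in 1:10) {
      a <- sample(labs, 1)
      b <- sample(labs, 1)
      p <- params_list[[sample(3, 1)]]
      v <- viability_map(.default = 1)
      ab <- cross_karyomorphs(a, b, p, v)
      ba <- cross_karyomorphs(b, a, p, v)
      expect_equal(ab, ba, ignore_attr = TRUE)
      expect_equal(sum(ab$prob), 1, tolerance = 1e-12)
      raw <- cross_karyomorphs(a, b, p, default_viability(), normalize = FALSE)
      expect_lte(sum(raw$prob), 1 + 1e-12)
      expect_equal(sum(raw$prob), attr(raw, "surviving_mass"), tolerance = 1e-12)
    }
  })
})

test_that("an all-lethal cross signals sterility without error", {
  out <- cross_karyomorphs("VII", "VII")
  expect_equal(nrow(out), 0)
  expect_true(attr(out, "sterile"))
  expect_equal(attr(out, "surviving_mass"), 0)
})

test_that("viability maps validate labels and ranges", {
  v <- viability_map(IX = 1)
  expect_equal(unname(v["IX"]), 1)
  expect_equal(unname(v["VIII"]), 0)
  expect_error(viability_map(X = 1), class = "quadrivalent_model_error")
  expect_error(viability_map(IX = 2), class = "quadrivalent_model_error")
  expect_equal(sum(default_viability() > 0), 5)
})

test_that("alternate plus adjacent-1 gametes can only ever rebuild types I-V", {
  withr::with_seed(23, {
    for (i in 1:5) {
      w <- runif(2)
      p <- segregation_params(w[1] / sum(w), w[2] / sum(w), 0)
      reach <- reachable_types("IV", "I", p, default_viability(), generations = 4)
      expect_true(all(reach$karyomorph %in% c("I", "II", "III", "IV", "V")))
    }
  })
})
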