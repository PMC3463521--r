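# independent oracles used to cross-check the implementation

# the six gamete classes as raw code pairs, bypassing the package's parsers
oracle_gametes <- list(
  c("M", "m"), c("T", "St"), c("M", "St"),
  c("m", "T"), c("M", "T"), c("m", "St")
)

# count distinct offspring multisets by brute force over unordered gamete
# pairs, using plain sorted strings rather than the package's label algebra
oracle_offspring_count <- function(code_pairs) {
  rank <- c(M = 1, m = 2, T = 3, St = 4)
  seen <- character(0)
  for (i in seq_along(code_pairs)) {
    for (j in i:length(code_pairs)) {
      four <- c(code_pairs[[i]], code_pairs[[j]])
      seen <- c(seen, paste(four[order(rank[four])], collapse = "."))
    }
  }
  length(unique(seen))
}

# dense grid search over the gamete-frequency simplex: the reference maximum
# of the viable-renormalised multinomial log-likelihood, written directly
# from the random-union zygote formulas (independent of the package path)
oracle_grid_loglik <- function(obs, step = 0.005) {
  s <- round(1 / step)
  parts <- vector("list", s + 1)
  for (a in 0:s) {
    rem <- s - a
    b <- rep(0:rem, times = rem - 0:rem + 1)
    cc <- unlist(lapply(0:rem, function(bb) 0:(rem - bb)), use.names = FALSE)
    parts[[a + 1]] <- cbind(a, b, cc)
  }
  m <- do.call(rbind, parts)
  f1 <- m[, 1] / s
  f3 <- m[, 2] / s
  f4 <- m[, 3] / s
  f2 <- 1 - f1 - f3 - f4

  pI <- f1^2
  pII <- 2 * f1 * f3
  pIII <- 2 * f1 * f4
  pIV <- 2 * f1 * f2 + 2 * f3 * f4
  pV <- 2 * f2 * f3
  mass <- pI + pII + pIII + pIV + pV

  n <- obs[c("I", "II", "III", "IV", "V")]
  n[is.na(n)] <- 0
  ll <- rep(0, length(f1))
  for (k in seq_along(n)) {
    if (n[k] > 0) {
      p <- switch(k, pI, pII, pIII, pIV, pV) / pmax(mass, 1e-300)
      contrib <- rep(-Inf, length(p))
      pos <- is.finite(p) & p > 0
      contrib[pos] <- n[k] * log(p[pos])
      ll <- ll + contrib
    }
  }
  ll[mass <= 0] <- -Inf
  i <- which.max(ll)
  list(loglik = ll[i], f = c(f1[i], f2[i], f3[i], f4[i]))
}

# expected next-generation frequencies by explicit double sum over genotype
# pairs and their offspring distributions
oracle_next_generation <- function(freqs, params, viability) {
  labs <- names(freqs)
  acc <- numeric(0)
  for (a in labs) {
    for (b in labs) {
      w <- freqs[[a]] * freqs[[b]]
      if (w <= 0) next
      off <- cross_karyomorphs(a, b, params,
                               viability = viability_map(.default = 1),
                               normalize = FALSE)
      for (r in seq_len(nrow(off))) {
        lab <- off$karyomorph[r]
        acc[lab] <- (if (is.na(acc[lab])) 0 else acc[lab]) + w * off$prob[r]
      }
    }
  }
  acc <- acc * viability_of_oracle(viability, names(acc))
  acc[acc > 0] / sum(acc)
}

viability_of_oracle <- function(viability, labels) {
  v <- unname(viability[labels])
  v[is.na(v)] <- 0
  v
}

# shorthand: counts fixture pooled into a named vector over karyomorphs
pooled_counts <- function(counts = example_karyomorph_counts()) {
  tapply(counts$count, counts$karyomorph, sum)
}
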