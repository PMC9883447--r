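test_that("allele frequencies come from non-missing genotypes, both marker types", {
  # pop of genotypes {AA, Aa, aa} -> p_alt = 0.5
  g <- snp_genotypes(dos(matrix(c(0L, 1L, 2L), 3, 1)))
  meta <- toy_meta(rep("A", 3))
  af <- allele_frequencies(g, meta)
  expect_equal(unname(af$freq[[1]]["A", "alt"]), 0.5)

  # microsat alleles {138 x 3, 142 x 1} -> p = (0.75, 0.25)
  gm <- microsat_genotypes(dos(matrix(c(138L, 138L), 2, 1)),
                           dos(matrix(c(138L, 142L), 2, 1)))
  afm <- allele_frequencies(gm, toy_meta(rep("A", 2)))
  expect_equal(unname(afm$freq[[1]]["A", ]), c(0.75, 0.25))

  # all genotypes missing at (pop, locus) -> flagged absent (n = 0)
  d <- dos(rbind(c(0L, NA), c(1L, NA), c(2L, 1L), c(0L, 1L)))
  meta2 <- toy_meta(rep(c("A", "B"), each = 2))
  af2 <- allele_frequencies(snp_genotypes(d), meta2)
  expect_equal(unname(af2$n["A", 2]), 0)
  expect_true(all(is.nan(af2$freq[[2]]["A", ])))
})

test_that("Nei-Chesser H_S matches hand evaluation; monomorphic F undefined", {
  # 10 individuals: 5 het + 5 hom-ref; H_O = 0.5, ref frequency 0.75
  g <- snp_genotypes(dos(matrix(c(rep(1L, 5), rep(0L, 5)), 10, 1)))
  meta <- toy_meta(rep("A", 10))
  bs <- basic_stats(g, meta)
  expect_equal(bs$per_population$Ho, 0.5)
  expect_equal(bs$per_population$Hs,
               (10 / 9) * (1 - (0.75^2 + 0.25^2) - 0.5 / 20),
               tolerance = 1e-12)
  expect_equal(bs$per_population$Hs, 0.38889, tolerance = 1e-4)

  # monomorphic locus: H_O = H_S = 0, F_IS missing (never zero)
  gm <- snp_genotypes(dos(matrix(0L, 6, 1)))
  bsm <- basic_stats(gm, toy_meta(rep(c("A", "B"), each = 3)))
  expect_equal(bsm$per_population$Ho, c(0, 0))
  expect_equal(bsm$per_population$Hs, c(0, 0))
  expect_true(all(is.na(bsm$per_population$Fis)))
  expect_true(is.na(bsm$overall["Fis"]))
})

test_that("two pops fixed for alternate alleles: Wahlund direction, theta = 1", {
  d <- dos(rbind(matrix(0L, 5, 4), matrix(2L, 5, 4)))
  g <- snp_genotypes(d)
  meta <- toy_meta(rep(c("A", "B"), each = 5))
  bs <- basic_stats(g, meta)
  expect_equal(unname(bs$overall["Hs"]), 0)
  expect_gt(unname(bs$overall["Ht"]), 0)
  th <- pairwise_fst(g, meta)
  expect_equal(unname(th$matrix["A", "B"]), 1)
  beta <- population_specific_fst(g, meta)
  expect_equal(beta$per_population$Beta, c(1, 1))
})

test_that("H_T exceeds mean H_S under differentiation (Wahlund direction)", {
  set.seed(3)
  for (rep in 1:5) {
    L <- 30
    p0 <- runif(L, 0.1, 0.9)
    f <- 0.1
    d <- do.call(rbind, lapply(1:4, function(k) {
      pk <- rbeta(L, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
      matrix(rbinom(10 * L, 2, rep(pk, each = 10)), 10, L)
    }))
    g <- snp_genotypes(dos(d))
    meta <- toy_meta(rep(c("A", "B", "C", "D"), each = 10))
    bs <- basic_stats(g, meta)
    expect_gte(unname(bs$overall["Ht"]), unname(bs$overall["Hs"]) - 1e-12)
  }
})

test_that("rarefied allelic richness matches the hypergeometric sums", {
  # counts (5,5), g = 2 -> 2 - 2*C(5,2)/C(10,2) = 1.5556
  g <- snp_genotypes(dos(matrix(1L, 5, 1)))  # 5 hets: counts (5,5)
  meta <- toy_meta(rep("A", 5))
  ar <- allelic_richness(g, meta, g_copies = 2)
  expect_equal(ar$Ar, 2 - 2 * choose(5, 2) / choose(10, 2), tolerance = 1e-12)
  expect_equal(ar$Ar, 1.5556, tolerance = 1e-4)

  # monomorphic: counts (10, 0) -> A_R = 1 for any g
  gm <- snp_genotypes(dos(matrix(0L, 5, 1)))
  expect_equal(allelic_richness(gm, meta, g_copies = 4)$Ar, 1)

  # g equal to total copies -> observed allele count
  expect_equal(allelic_richness(g, meta, g_copies = 10)$Ar, 2)
  expect_error(allelic_richness(g, meta, g_copies = 1), ">= 2")
})

test_that("Beta equals the exhaustive allele-matching oracle on toy data", {
  # pop A near-fixed, pop B at 0.5; 6 individuals, 2 loci
  d <- dos(rbind(c(2L, 2L), c(2L, 2L), c(1L, 2L),
                 c(1L, 0L), c(0L, 1L), c(1L, 2L)))
  g <- snp_genotypes(d)
  meta <- toy_meta(rep(c("A", "B"), each = 3))
  est <- population_specific_fst(g, meta)

  # oracle: enumerate allele copies per pop per locus
  to_alleles <- function(dosages) {
    unlist(lapply(dosages, function(x) c(rep("alt", x), rep("ref", 2 - x))))
  }
  num <- den <- c(A = 0, B = 0)
  for (l in 1:2) {
    aA <- to_alleles(d[1:3, l]); aB <- to_alleles(d[4:6, l])
    mwA <- matching_within_oracle(aA)
    mwB <- matching_within_oracle(aB)
    mb <- matching_between_oracle(aA, aB)
    num <- num + c(A = mwA - mb, B = mwB - mb)
    den <- den + (1 - mb)
  }
  oracle <- num / den
  expect_equal(est$per_population$Beta, unname(oracle), tolerance = 1e-9)
  expect_gt(est$per_population$Beta[1], est$per_population$Beta[2])
})

test_that("identical panmictic populations give Beta near zero", {
  set.seed(5)
  L <- 800
  p <- runif(L, 0.2, 0.8)
  d <- matrix(rbinom(120 * L, 2, rep(p, each = 120)), 120, L)
  g <- snp_genotypes(dos(d))
  meta <- toy_meta(rep(c("A", "B", "C"), each = 40))
  est <- population_specific_fst(g, meta)
  expect_true(all(abs(est$per_population$Beta) < 0.01))
})

test_that("H_S envelope bounds follow the printed formula", {
  # p = 0.5, f_IT = 0.05, N = 196
  env <- hs_envelope_bounds(0.5, 0.05, 196)
  expect_equal(env$center, 0.475)
  half <- 2 * sqrt(2 * 0.5 * 0.5 * 1.05 / 196)
  expect_equal(env$upper - env$center, half, tolerance = 1e-12)
  expect_equal(c(env$lower, env$upper), c(0.3715, 0.5785), tolerance = 1e-4)

  # p = 0 -> (0, 0); f = 0 -> symmetric around 2p(1-p)
  env0 <- hs_envelope_bounds(0, 0.1, 50)
  expect_equal(c(env0$center, env0$lower, env0$upper), c(0, 0, 0))
  envs <- hs_envelope_bounds(0.5, 0, 100)
  expect_equal(envs$center, 0.5)
  expect_equal(envs$center - envs$lower, envs$upper - envs$center)
  expect_error(hs_envelope_bounds(0.5, 0, 0), ">= 1")

  # the variance-derivation variant is narrower for f_IT > 0
  alt <- hs_envelope_bounds(0.5, 0.05, 196, radical_sign = "minus")
  expect_lt(alt$upper - alt$lower, env$upper - env$lower)
})

test_that("bootstrap CIs: degenerate zero width, seeded determinism", {
  # all loci identical -> zero-width CI at the estimate
  d <- dos(matrix(rep(c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 1L), 25), 8, 25))
  g <- snp_genotypes(d)
  meta <- toy_meta(rep(c("A", "B"), each = 4))
  ci <- bootstrap_ci(g, meta, "fst", n_boot = 50, seed = 9)
  expect_equal(ci$lower, ci$estimate, tolerance = 1e-12)
  expect_equal(ci$upper, ci$estimate, tolerance = 1e-12)

  ci2 <- bootstrap_ci(g, meta, "fst", n_boot = 50, seed = 9)
  expect_identical(ci, ci2)
  expect_error(bootstrap_ci(g, meta, "fst", n_boot = 1), "n_boot")
})

test_that("statistics are invariant to ref/alt orientation and locus order", {
  set.seed(13)
  L <- 40
  d <- matrix(rbinom(30 * L, 2, rep(runif(L, 0.1, 0.9), each = 30)), 30, L)
  d[sample(length(d), 40)] <- NA
  g <- snp_genotypes(dos(d))
  meta <- toy_meta(rep(c("A", "B", "C"), each = 10))
  flip <- sample(L, 15)
  d2 <- d
  d2[, flip] <- 2L - d2[, flip]
  g2 <- snp_genotypes(dos(d2))

  bs1 <- basic_stats(g, meta); bs2 <- basic_stats(g2, meta)
  expect_equal(bs1$overall, bs2$overall, tolerance = 1e-12)
  expect_equal(pairwise_fst(g, meta)$matrix, pairwise_fst(g2, meta)$matrix,
               tolerance = 1e-12)
  expect_equal(population_specific_fst(g, meta)$per_population,
               population_specific_fst(g2, meta)$per_population,
               tolerance = 1e-12)

  # locus permutation leaves summary statistics unchanged
  perm <- sample(L)
  g3 <- snp_genotypes(dos(d[, perm], loci = colnames(g$dosage)[perm]))
  bs3 <- basic_stats(g3, meta)
  expect_equal(bs1$overall, bs3$overall, tolerance = 1e-12)
})

test_that("deleting a monomorphic locus leaves F-statistics unchanged", {
  set.seed(17)
  d <- cbind(matrix(rbinom(20 * 10, 2, 0.4), 20, 10), rep(0L, 20))
  g_with <- snp_genotypes(dos(d))
  g_without <- snp_genotypes(dos(d[, 1:10]))
  meta <- toy_meta(rep(c("A", "B"), each = 10))
  expect_equal(pairwise_fst(g_with, meta)$matrix,
               pairwise_fst(g_without, meta)$matrix, tolerance = 1e-12)
  expect_equal(basic_stats(g_with, meta)$overall[c("Fis", "Fst")],
               basic_stats(g_without, meta)$overall[c("Fis", "Fst")],
               tolerance = 1e-12)
})

test_that("multiallelic path on biallelic data equals the biallelic path", {
  set.seed(19)
  L <- 15
  d <- matrix(rbinom(24 * L, 2, rep(runif(L, 0.2, 0.8), each = 24)), 24, L)
  d[sample(length(d), 20)] <- NA
  g_snp <- snp_genotypes(dos(d))
  # encode the same data as a 2-allele microsatellite (alleles 101 = alt, 99 = ref)
  a1 <- ifelse(d >= 1L, 101L, 99L)
  a2 <- ifelse(d == 2L, 101L, 99L)
  a1[is.na(d)] <- NA; a2[is.na(d)] <- NA
  g_ms <- microsat_genotypes(dos(a1), dos(a2))
  meta <- toy_meta(rep(c("A", "B", "C"), each = 8))
  expect_equal(basic_stats(g_snp, meta)$overall,
               basic_stats(g_ms, meta)$overall, tolerance = 1e-12)
  expect_equal(pairwise_fst(g_snp, meta)$matrix,
               pairwise_fst(g_ms, meta)$matrix, tolerance = 1e-12)
  expect_equal(population_specific_fst(g_snp, meta)$per_population$Beta,
               population_specific_fst(g_ms, meta)$per_population$Beta,
               tolerance = 1e-12)
})
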