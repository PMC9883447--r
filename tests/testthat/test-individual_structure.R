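test_that("PCA separates clusters and is invariant to duplication and order", {
  d <- dos(rbind(matrix(0L, 5, 20), matrix(2L, 5, 20)))
  g <- snp_genotypes(d)
  pc <- genotype_pca(g, n_axes = 3)
  s1 <- pc$scores[1:5, 1]; s2 <- pc$scores[6:10, 1]
  expect_equal(stats::sd(s1), 0, tolerance = 1e-10)
  expect_equal(stats::sd(s2), 0, tolerance = 1e-10)
  expect_gt(abs(mean(s1) - mean(s2)), 1)

  # duplicating every individual leaves axis directions unchanged
  d2 <- rbind(d, d)
  rownames(d2) <- sprintf("j%02d", 1:20)
  pc2 <- genotype_pca(snp_genotypes(d2), n_axes = 2)
  expect_equal(abs(stats::cor(pc2$scores[1:10, 1], pc$scores[, 1])), 1,
               tolerance = 1e-9)

  # locus order permutation leaves scores unchanged
  set.seed(59)
  dd <- dos(matrix(rbinom(200, 2, 0.4), 10, 20))
  perm <- sample(20)
  pa <- genotype_pca(snp_genotypes(dd), n_axes = 3)
  pb <- genotype_pca(snp_genotypes(dd[, perm]), n_axes = 3)
  expect_equal(unname(abs(diag(stats::cor(pa$scores, pb$scores)))), rep(1, 3),
               tolerance = 1e-9)

  expect_warning(genotype_pca(snp_genotypes(
    dos(cbind(matrix(rbinom(20, 2, .5), 10, 2), rep(NA_integer_, 10)))),
    n_axes = 2), "all-missing")
})

test_that("PCA axis variances are ordered and bounded", {
  set.seed(61)
  g <- snp_genotypes(dos(matrix(rbinom(600, 2, 0.3), 20, 30)))
  pc <- genotype_pca(g, n_axes = 5)
  expect_true(all(diff(pc$var_fraction) <= 1e-12))
  expect_true(all(pc$var_fraction >= 0 & pc$var_fraction <= 1))
  expect_lte(sum(pc$var_fraction), 1 + 1e-9)
})

test_that("k-means on 3 PCs recovers 4 simulated clusters (>= 95%)", {
  des <- data.frame(population = as.character(1:4),
                    country = as.character(1:4), n = rep(15, 4))
  ds <- simulate_dataset(sim_config(design = des, n_snps = 2000,
                                    n_microsats = 2, f_ct = 0.06, f_sc = 0),
                         seed = 3)
  pc <- genotype_pca(ds$snp, n_axes = 3)
  set.seed(3)
  km <- stats::kmeans(pc$scores, centers = 4, nstart = 25)
  tab <- table(km$cluster, ds$meta$population)
  expect_gte(sum(apply(tab, 2, max)) / sum(tab), 0.95)
})

test_that("admixture: K = 1 closed form, separation, determinism, invariants", {
  # K = 1: cross-entropy ~ entropy of the global class frequencies
  set.seed(67)
  d <- dos(matrix(rbinom(200 * 60, 2, 0.5), 200, 60))
  g <- snp_genotypes(d)
  f1 <- admixture_fit(g, K = 1, n_reps = 2, seed = 67)[[1]]
  expect_true(all(f1$Q == 1))
  cls <- c(mean(d == 0), mean(d == 1), mean(d == 2))
  expect_equal(f1$cross_entropy, -sum(cls * log(cls)), tolerance = 0.02)

  # two fixed populations at 100 loci: near-vertex ancestries
  d2 <- dos(rbind(matrix(0L, 10, 100), matrix(2L, 10, 100)))
  g2 <- snp_genotypes(d2)
  fits <- admixture_fit(g2, K = 2, n_reps = 3, seed = 5)
  best <- fits[[which.min(vapply(fits, `[[`, 1, "cross_entropy"))]]
  expect_gt(mean(apply(best$Q, 1, max)), 0.99)
  # cluster genotype-class profiles near (1,0,0) and (0,0,1)
  g_first <- best$G[, 1:3]
  expect_true(all(apply(g_first, 1, max) > 0.98))

  # same data/seed/mask -> identical fit bit-for-bit
  fits_b <- admixture_fit(g2, K = 2, n_reps = 3, seed = 5)
  expect_identical(fits, fits_b)

  # row-stochastic Q, valid G, non-increasing objective, CE >= 0
  for (f in fits) {
    expect_equal(unname(rowSums(f$Q)), rep(1, 20), tolerance = 1e-9)
    expect_true(all(f$Q >= -1e-12))
    trip <- matrix(f$G[1, ], nrow = 3)
    expect_equal(colSums(trip), rep(1, 100), tolerance = 1e-9)
    expect_true(all(diff(f$objective_trace) <= 1e-9))
    expect_gte(f$cross_entropy, 0)
  }
  expect_error(admixture_fit(g2, K = 30, seed = 1), "exceeds")
})

test_that("K selection follows the plateau rule on constructed entropies", {
  # strictly decreasing then flat from K = 4
  ent <- do.call(rbind, lapply(1:6, function(k) {
    data.frame(K = k, rep = 1:4,
               cross_entropy = c(1, .8, .6, .4, .4, .4)[k] + c(0, 1e-4, -1e-4, 2e-4))
  }))
  expect_equal(select_k(ent)$k_star, 4)

  # flat entropies -> K* = 1
  flat <- transform(ent, cross_entropy = 0.5 + rep(c(0, 1e-5, -1e-5, 0), 6))
  expect_equal(select_k(flat)$k_star, 1)

  expect_warning(sk <- select_k(data.frame(K = 3, rep = 1:3,
                                           cross_entropy = c(.5, .6, .7))),
                 "single K")
  expect_equal(sk$k_star, 3)
})

test_that("cluster relabeling and concordance are label-switch invariant", {
  set.seed(71)
  q <- matrix(runif(40), 10, 4)
  q <- q / rowSums(q)
  perm <- c(3, 1, 4, 2)
  expect_equal(match_clusters(q, q[, perm]), q, tolerance = 1e-12)
  expect_equal(popresolve:::assignment_concordance(q, q[, perm]), 1)
})

test_that("subsampling at full size gives concordance 1; oversize errors", {
  d <- dos(rbind(matrix(0L, 8, 60), matrix(2L, 8, 60)))
  g <- snp_genotypes(d)
  ex <- snp_subsample_experiment(g, sizes = 60, K = 2, n_reps = 2, seed = 2)
  expect_equal(ex$per_size$concordance, 1)
  expect_error(snp_subsample_experiment(g, sizes = 100, K = 2, seed = 2),
               "size exceeds")
})

test_that("assignment indices center within populations; degenerate flagged", {
  # genetically identical individuals -> all AIc = 0, flagged
  d <- dos(matrix(1L, 12, 10))
  g <- snp_genotypes(d)
  meta <- toy_meta(rep(c("A", "B"), each = 6),
                   sex = rep(c("M", "F"), 6))
  res <- sexbias_test(g, meta, n_perm = 19, seed = 1)
  expect_true(res$degenerate)
  expect_equal(unname(res$maic), c(0, 0))
  expect_equal(res$t, 0)

  # AIc sums to ~0 within each population by construction
  set.seed(73)
  d2 <- dos(matrix(rbinom(240, 2, 0.4), 24, 10))
  g2 <- snp_genotypes(d2)
  meta2 <- toy_meta(rep(c("A", "B"), each = 12),
                    sex = rep(c("M", "F"), 12))
  res2 <- sexbias_test(g2, meta2, n_perm = 19, seed = 1)
  sums <- tapply(res2$aic$AIc, res2$aic$population, sum)
  expect_equal(as.numeric(sums), c(0, 0), tolerance = 1e-9)
  expect_false(res2$degenerate)
  expect_true(is.finite(res2$t))

  expect_error(sexbias_test(g2, toy_meta(rep("A", 24))), "each known sex")
})

test_that("microsatellite and SNP assignment indices use the same model", {
  # encode identical biallelic data both ways: AI must match exactly
  set.seed(79)
  d <- matrix(rbinom(200, 2, 0.45), 20, 10)
  g_snp <- snp_genotypes(dos(d))
  a1 <- ifelse(d >= 1L, 101L, 99L); a2 <- ifelse(d == 2L, 101L, 99L)
  g_ms <- microsat_genotypes(dos(a1), dos(a2))
  meta <- toy_meta(rep(c("A", "B"), each = 10), sex = rep(c("M", "F"), 10))
  r1 <- sexbias_test(g_snp, meta, n_perm = 9, seed = 1)
  r2 <- sexbias_test(g_ms, meta, n_perm = 9, seed = 1)
  expect_equal(r1$aic$AI, r2$aic$AI, tolerance = 1e-9)
})
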