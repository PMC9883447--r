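test_that("simulation is deterministic given a seed", {
  cfg <- sim_config(design = data.frame(population = c("a", "b"),
                                        country = c("X", "Y"), n = c(5, 6)),
                    n_snps = 50, n_microsats = 3)
  d1 <- simulate_dataset(cfg, seed = 123)
  d2 <- simulate_dataset(cfg, seed = 123)
  expect_identical(d1$snp$dosage, d2$snp$dosage)
  expect_identical(d1$microsat$a1, d2$microsat$a1)
  expect_identical(d1$truth$p_pop, d2$truth$p_pop)
  d3 <- simulate_dataset(cfg, seed = 124)
  expect_false(identical(d1$snp$dosage, d3$snp$dosage))
})

test_that("no differentiation by construction when F = 0", {
  des <- data.frame(population = as.character(1:4),
                    country = as.character(1:4), n = rep(20, 4))
  ds <- simulate_dataset(sim_config(design = des, n_snps = 5000,
                                    n_microsats = 2, f_ct = 0, f_sc = 0),
                         seed = 9)
  expect_identical(unname(ds$truth$p_pop[, 1]), ds$truth$p_anc)
  m <- pairwise_fst(ds$snp, ds$meta)$matrix
  expect_lt(abs(mean(m[upper.tri(m)])), 0.005)
})

test_that("single-level model recovers its F parameter", {
  des <- data.frame(population = as.character(1:5),
                    country = as.character(1:5), n = rep(20, 5))
  ds <- simulate_dataset(sim_config(design = des, n_snps = 5000,
                                    n_microsats = 2, f_ct = 0.10, f_sc = 0),
                         seed = 10)
  m <- pairwise_fst(ds$snp, ds$meta)$matrix
  expect_equal(mean(m[upper.tri(m)]), 0.10, tolerance = 0.01)
  beta <- population_specific_fst(ds$snp, ds$meta)
  expect_equal(beta$overall, 0.10, tolerance = 0.01)
})

test_that("truth record reproduces realized latent frequencies", {
  des <- data.frame(population = c("a", "b"), country = c("X", "Y"),
                    n = c(50, 50))
  ds <- simulate_dataset(sim_config(design = des, n_snps = 2000,
                                    n_microsats = 2, f_ct = 0.05, f_sc = 0.02),
                         seed = 12)
  # sample allele frequencies track the recorded latent p_pop
  af <- allele_frequencies(ds$snp, ds$meta)
  p_hat <- vapply(af$freq, function(f) f["a", "alt"], numeric(1))
  expect_gt(stats::cor(p_hat, ds$truth$p_pop[, "a"]), 0.97)
})

test_that("read-depth masking matches the negative-binomial tail mass", {
  des <- data.frame(population = "a", country = "X", n = 60)
  cfg <- sim_config(design = des, n_snps = 400, n_microsats = 1,
                    depth_mean = 5, depth_dispersion = 4)
  ds <- simulate_dataset(cfg, seed = 14)
  gd <- simulate_read_depths(ds$snp, cfg, seed = 15)
  mk <- mask_low_quality_genotypes(gd, filter_config())
  frac_depth <- mk$masked_depth / length(gd$dosage)
  expected <- pnbinom(7, mu = 5, size = 4)
  expect_equal(frac_depth, expected, tolerance = 0.02)

  # high coverage: < 1% masked by the depth rule
  cfg50 <- sim_config(design = des, n_snps = 400, n_microsats = 1,
                      depth_mean = 50, depth_dispersion = 20)
  gd50 <- simulate_read_depths(ds$snp, cfg50, seed = 16)
  mk50 <- mask_low_quality_genotypes(gd50, filter_config())
  expect_lt(mk50$masked_depth / length(gd50$dosage), 0.01)
  expect_lt(pnbinom(7, mu = 50, size = 20), 0.01)

  # zero error rate: homozygote reads carry a single allele
  cfg0 <- sim_config(design = des, n_snps = 100, n_microsats = 1,
                     error_rate = 0)
  gd0 <- simulate_read_depths(ds$snp, cfg0, seed = 17)
  hom_ref <- !is.na(ds$snp$dosage[, 1:100]) & ds$snp$dosage[, 1:100] == 0L
  expect_true(all(gd0$depths$alt[, 1:100][hom_ref] == 0L))
})

test_that("migrant injection: no-op at fraction 0, detectable at 0.4", {
  des <- data.frame(population = c("hub", "src", "out"),
                    country = c("X", "Y", "Z"), n = c(20, 20, 20))
  cfg <- sim_config(design = des, n_snps = 1500, n_microsats = 2,
                    f_ct = 0.10, f_sc = 0)
  ds <- simulate_dataset(cfg, seed = 18)
  expect_identical(inject_migrants(ds, "hub", "src", 0)$snp$dosage,
                   ds$snp$dosage)
  expect_error(inject_migrants(ds, "hub", "hub", 0.2), "must differ")

  ds2 <- inject_migrants(ds, "hub", "src", 0.4, seed = 19)
  expect_equal(length(ds2$truth$migrants), 8)
  # admixture at K = 2 on hub + src assigns migrants to the source cluster
  keep <- ds2$meta$population %in% c("hub", "src")
  g2 <- subset_snps(ds2$snp, individuals = which(keep))
  fits <- admixture_fit(g2, K = 2, n_reps = 3, seed = 20)
  best <- fits[[which.min(vapply(fits, `[[`, 1, "cross_entropy"))]]
  src_rows <- which(rownames(best$Q) %in%
                      ds2$meta$individual[ds2$meta$population == "src"])
  mig_rows <- which(rownames(best$Q) %in% ds2$truth$migrants)
  src_cluster <- which.max(colMeans(best$Q[src_rows, , drop = FALSE]))
  expect_gt(mean(best$Q[mig_rows, src_cluster]), 0.9)
})

test_that("stepping-stone chain accumulates differentiation with distance", {
  ds <- simulate_stepping_stone(n_demes = 6, n_per_deme = 12, n_loci = 400,
                                f_step = 0.04, seed = 21)
  fst <- pairwise_fst(ds$snp, ds$meta)$matrix
  near <- mean(fst[cbind(1:5, 2:6)])
  far <- fst[1, 6]
  expect_gt(far, near)
})

test_that("sex-biased dispersal raises migrant counts among males only", {
  des <- data.frame(population = as.character(1:5),
                    country = as.character(1:5), n = rep(20, 5))
  ds <- simulate_dataset(sim_config(design = des, n_snps = 300,
                                    n_microsats = 1, f_ct = 0.1, f_sc = 0),
                         seed = 22)
  ds2 <- apply_sex_biased_dispersal(ds, male_rate = 0.5, female_rate = 0,
                                    seed = 23)
  mig_sex <- ds2$meta$sex[ds2$meta$individual %in% ds2$truth$migrants]
  expect_true(all(mig_sex == "M"))
  expect_gt(length(ds2$truth$migrants), 0)
})
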