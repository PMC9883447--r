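# Monte-Carlo experiments that validate the estimators and tests under the
# study's conditions. Each experiment fixes its design once (documented in
# the methods vignette) and takes only a replicate count and a seed, so the
# analysis scripts, the test suite and the acceptance script all run the
# same protocol.

#' Hierarchical parameter recovery on the paper-like design
#'
#' Simulates the full 19-population / 7-country design (study sample sizes,
#' 4994 SNPs, F_CT = 0.058, F_SC = 0.019, complete matrices) and re-estimates
#' the hierarchical F-statistics, replicate by replicate.
#'
#' @param n_replicates number of simulated datasets (default 20)
#' @param seed base seed
#' @return list: `per_replicate` (data frame Fsc, Fct), `mean_fsc`,
#'   `mean_fct`, `truth` (c(0.019, 0.058))
#' @export
experiment_param_recovery <- function(n_replicates = 20, seed = 1) {
  cfg <- paper_like_config(with_missingness = FALSE)
  res <- lapply(seq_len(n_replicates), function(r) {
    ds <- simulate_dataset(cfg, seed = child_seed(seed, r))
    hierarchical_fstats(ds$snp, ds$meta)$fstats[c("Fsc", "Fct")]
  })
  per <- as.data.frame(do.call(rbind, res))
  list(per_replicate = per,
       mean_fsc = mean(per$Fsc), mean_fct = mean(per$Fct),
       truth = c(fsc = cfg$f_sc, fct = cfg$f_ct))
}

#' K-selection replicates on a four-deme design
#'
#' Four equally sized demes (40 individuals each, matching the study's main
#' cluster sizes) at F = 0.058 with 5000 SNPs; each replicate simulates a
#' dataset, scans K = 1..6 with `n_reps` maskings per K, and applies the
#' plateau rule.
#'
#' @param n_replicates number of simulated datasets (default 5)
#' @param n_reps repetitions per K (default 2)
#' @param seed base seed
#' @return list: `k_star` (per replicate), `fraction_correct` (K* == 4)
#' @export
experiment_k_selection <- function(n_replicates = 5, n_reps = 2, seed = 1) {
  des <- data.frame(population = as.character(1:4),
                    country = as.character(1:4), n = rep(40, 4))
  cfg <- sim_config(design = des, n_snps = 5000, n_microsats = 2,
                    f_ct = 0.058, f_sc = 0)
  k_star <- vapply(seq_len(n_replicates), function(r) {
    ds <- simulate_dataset(cfg, seed = child_seed(seed, 300 + r))
    sc <- admixture_scan(ds$snp, k_range = 1:6, n_reps = n_reps,
                         seed = child_seed(seed, 400 + r))
    select_k(sc$entropy)$k_star
  }, numeric(1))
  list(k_star = k_star, fraction_correct = mean(k_star == 4))
}

#' SNP-subsampling resolution replicates on the paper-like design
#'
#' The paper-like preset (19 populations, concentrated missingness) is fit
#' at K = 4 on all loci and on random subsets; concordance of individual
#' hard assignments with the full-data fit is averaged over replicates.
#'
#' @param sizes locus subset sizes (default c(1000, 100))
#' @param n_replicates number of simulated datasets (default 3)
#' @param n_reps repetitions per fit (default 3)
#' @param seed base seed
#' @return list: `per_replicate` (size x replicate concordances),
#'   `mean_concordance` (named by size)
#' @export
experiment_resolution <- function(sizes = c(1000, 100), n_replicates = 3,
                                  n_reps = 3, seed = 1) {
  cfg <- paper_like_config()
  conc <- vapply(seq_len(n_replicates), function(r) {
    ds <- simulate_dataset(cfg, seed = child_seed(seed, 500 + r))
    ex <- snp_subsample_experiment(ds$snp, sizes = sizes, K = 4,
                                   n_reps = n_reps,
                                   seed = child_seed(seed, 600 + r))
    ex$per_size$concordance
  }, numeric(length(sizes)))
  conc <- matrix(conc, nrow = length(sizes),
                 dimnames = list(as.character(sizes), NULL))
  list(per_replicate = conc,
       mean_concordance = rowMeans(conc))
}

#' Type-I error of the Mantel test under independence
#'
#' Independent random distance matrices (12 labels); rejection rate at
#' alpha = 0.05 should sit near 0.05.
#'
#' @param n_sims simulated pairs (default 200)
#' @param n_perm permutations per test (default 199)
#' @param seed base seed
#' @return list: `rejection_rate`, `p_values`
#' @export
experiment_mantel_null <- function(n_sims = 200, n_perm = 199, seed = 1) {
  p <- vapply(seq_len(n_sims), function(s) {
    with_seed(child_seed(seed, 700 + s), {
      n <- 12
      m1 <- as.matrix(stats::dist(matrix(stats::runif(n * 3), n)))
      m2 <- as.matrix(stats::dist(matrix(stats::runif(n * 3), n)))
      dimnames(m1) <- dimnames(m2) <- list(seq_len(n), seq_len(n))
      mantel_test(dist_matrix(m1), dist_matrix(m2), n_perm = n_perm,
                  seed = child_seed(seed, 800 + s))$p
    })
  }, numeric(1))
  list(rejection_rate = mean(p <= 0.05), p_values = p)
}

#' Isolation-by-distance power and null calibration
#'
#' Power: 1-D stepping-stone chains (8 demes, drift per step) must yield
#' Mantel p < 0.05 in most replicates. Null: island-model simulations (no
#' geography) must reject at ~alpha.
#'
#' @param n_replicates replicates per arm (default 50)
#' @param seed base seed
#' @return list: `power`, `null_rejection_rate`
#' @export
experiment_ibd <- function(n_replicates = 50, seed = 1) {
  run_one <- function(r, f_step) {
    ds <- simulate_stepping_stone(n_demes = 8, n_per_deme = 10, n_loci = 300,
                                  f_step = f_step,
                                  seed = child_seed(seed, 900 + r))
    if (f_step == 0) {
      # island model: resample deme frequencies independently instead
      ds <- with_seed(child_seed(seed, 950 + r), {
        des <- data.frame(population = sprintf("deme%02d", 1:8),
                          country = sprintf("deme%02d", 1:8), n = rep(10, 8),
                          X = (0:7) * 100 / 111.195, Y = rep(0, 8))
        simulate_dataset(sim_config(design = des, n_snps = 300,
                                    n_microsats = 1, f_ct = 0.05, f_sc = 0),
                         seed = child_seed(seed, 960 + r))
      })
    }
    fst <- pairwise_fst(ds$snp, ds$meta)
    geo <- geographic_distances(ds$meta)
    ibd_analysis(fst, geo, n_perm = 199,
                 seed = child_seed(seed, 970 + r))$p
  }
  p_power <- vapply(seq_len(n_replicates), run_one, numeric(1),
                    f_step = 0.02)
  p_null <- vapply(seq_len(n_replicates), run_one, numeric(1), f_step = 0)
  list(power = mean(p_power < 0.05),
       null_rejection_rate = mean(p_null < 0.05))
}

#' Power of the sex-bias test under male-biased dispersal
#'
#' 10 populations x 20 individuals x 1000 SNPs at F = 0.1; males migrate
#' with probability 0.3, females not at all.
#'
#' @param n_replicates replicates (default 50)
#' @param male_rate male migration probability (default 0.3)
#' @param seed base seed
#' @return list: `power` (fraction with male mAIc < female and p < 0.05),
#'   `per_replicate`
#' @export
experiment_sexbias_power <- function(n_replicates = 50, male_rate = 0.3,
                                     seed = 1) {
  des <- data.frame(population = as.character(1:10),
                    country = as.character(1:10), n = rep(20, 10))
  cfg <- sim_config(design = des, n_snps = 1000, n_microsats = 1,
                    f_ct = 0.1, f_sc = 0)
  res <- lapply(seq_len(n_replicates), function(r) {
    ds <- simulate_dataset(cfg, seed = child_seed(seed, 1100 + r))
    ds <- apply_sex_biased_dispersal(ds, male_rate = male_rate,
                                     female_rate = 0,
                                     seed = child_seed(seed, 1200 + r))
    sb <- sexbias_test(ds$snp, ds$meta, n_perm = 199,
                       seed = child_seed(seed, 1300 + r))
    c(male_lower = unname(sb$maic["M"] < sb$maic["F"]),
      significant = unname(!is.na(sb$p_t) && sb$p_t < 0.05))
  })
  per <- do.call(rbind, res)
  list(power = mean(per[, "male_lower"] & per[, "significant"]),
       per_replicate = per)
}

#' Coverage of the bootstrap F_ST confidence interval
#'
#' Datasets of 6 populations x 10 individuals x 500 SNPs simulated at
#' F = 0.05; the bootstrap 95% CI for multi-locus Weir-Cockerham theta
#' should cover the generating F in ~95% of replicates.
#'
#' @param n_replicates replicates (default 200)
#' @param n_boot bootstrap draws per CI (default 1000, the workflow's
#'   standard bootstrap count)
#' @param seed base seed
#' @return list: `coverage`, `per_replicate`
#' @export
experiment_bootstrap_coverage <- function(n_replicates = 200, n_boot = 1000,
                                          seed = 1) {
  des <- data.frame(population = as.character(1:6),
                    country = as.character(1:6), n = rep(10, 6))
  cfg <- sim_config(design = des, n_snps = 500, n_microsats = 1,
                    f_ct = 0.05, f_sc = 0)
  cover <- vapply(seq_len(n_replicates), function(r) {
    ds <- simulate_dataset(cfg, seed = child_seed(seed, 1400 + r))
    ci <- bootstrap_ci(ds$snp, ds$meta, "fst", n_boot = n_boot,
                       seed = child_seed(seed, 1500 + r))
    ci$lower <= 0.05 && ci$upper >= 0.05
  }, logical(1))
  list(coverage = mean(cover), per_replicate = cover)
}

#' Missingness-mechanism reproduction
#'
#' One population sequenced at low depth; after depth-aware filtering, its
#' heterozygotes are depleted, so per-population F_IS correlates positively
#' with the missing fraction, and removing that population attenuates the
#' correlation.
#'
#' @param seed base seed
#' @return list: `sensitivity` ([missingness_sensitivity()] output),
#'   `fis_correlation`, `attenuated_correlation`
#' @export
experiment_missingness_mechanism <- function(seed = 1) {
  des <- data.frame(population = as.character(1:8),
                    country = as.character(1:8), n = rep(15, 8))
  dm <- stats::setNames(rep(30, 8), des$population)
  dm["1"] <- 8
  cfg <- sim_config(design = des, n_snps = 3000, n_microsats = 1,
                    f_ct = 0.05, f_sc = 0, depth_mean = dm,
                    depth_dispersion = 3)
  ds <- simulate_dataset(cfg, seed = child_seed(seed, 1600))
  gd <- simulate_read_depths(ds$snp, cfg, meta = ds$meta,
                             seed = child_seed(seed, 1601))
  filt <- run_filter_pipeline(gd, filter_config())
  ms <- missingness_sensitivity(filt$genotypes, ds$meta)
  fis_r <- ms$correlations$r[ms$correlations$statistic == "Fis"]
  att <- ms$influence$r[ms$influence$dropped == "1" &
                          ms$influence$statistic == "Fis"]
  list(sensitivity = ms, fis_correlation = fis_r,
       attenuated_correlation = att)
}
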