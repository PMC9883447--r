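# End-to-end marker comparison: the full study workflow over one SNP and one
# microsatellite dataset sharing individuals, producing a machine-readable
# report in which every number traces to a module function and a seed.

pearson_with_p <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  }
  ct <- stats::cor.test(x[ok], y[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Per-population summary table for one marker set
#'
#' H_O, H_S, F_IS, rarefied allelic richness and population-specific F_ST
#' side by side, one row per population.
#'
#' @inheritParams allele_frequencies
#' @return data frame: population, Ho, Hs, Fis, Ar, Beta
#' @export
population_table <- function(g, meta) {
  bs <- basic_stats(g, meta)
  ar <- allelic_richness(g, meta)
  beta <- population_specific_fst(g, meta)
  out <- bs$per_population
  out$Ar <- ar$Ar[match(out$population, ar$population)]
  out$Beta <- beta$per_population$Beta[
    match(out$population, beta$per_population$population)]
  out
}

#' Sensitivity of diversity statistics to per-population missingness
#'
#' Pearson correlation (t approximation) between the per-population missing
#' fraction and H_O, H_S, F_IS, plus leave-one-population-out influence runs
#' showing whether a single high-missingness population drives each
#' correlation.
#'
#' @param g [snp_genotypes()]
#' @inheritParams allele_frequencies
#' @return list: `per_population` (missing fraction + statistics),
#'   `correlations` (statistic, r, p; `NA` + flag when missingness is
#'   absent/uniform), `influence` (correlations after dropping each
#'   population), `flag`
#' @export
missingness_sensitivity <- function(g, meta) {
  meta <- align_metadata(g, meta)
  pops <- unique(meta$population)
  miss <- vapply(pops, function(p) {
    mean(is.na(g$dosage[meta$population == p, , drop = FALSE]))
  }, numeric(1))
  tab <- population_table(g, meta)
  tab$missing <- miss[tab$population]
  flag <- if (all(miss == 0)) "no_missingness"
          else if (stats::sd(miss) == 0) "uniform_missingness"
          else NA_character_
  cors <- do.call(rbind, lapply(c("Ho", "Hs", "Fis"), function(s) {
    ct <- if (is.na(flag)) pearson_with_p(tab$missing, tab[[s]])
          else list(r = NA_real_, p = NA_real_, n = nrow(tab))
    data.frame(statistic = s, r = ct$r, p = ct$p)
  }))
  influence <- NULL
  if (is.na(flag)) {
    influence <- do.call(rbind, lapply(seq_along(pops), function(i) {
      sub <- tab[-i, ]
      do.call(rbind, lapply(c("Ho", "Hs", "Fis"), function(s) {
        ct <- pearson_with_p(sub$missing, sub[[s]])
        data.frame(dropped = pops[i], statistic = s, r = ct$r, p = ct$p)
      }))
    }))
  }
  list(per_population = tab, correlations = cors, influence = influence,
       flag = flag)
}

#' Run the full microsatellite-versus-SNP comparison
#'
#' Executes the study workflow on both marker sets restricted to their
#' shared individuals: per-population statistics, bootstrap CIs, pairwise
#' F_ST with marker-to-marker Mantel test, isolation by distance,
#' chord-distance BIONJ trees, hierarchical F-statistics, sex-bias tests
#' (with between-marker AIc correlation), and optionally the admixture scans
#' and SNP-subsampling experiment.
#'
#' @param snp [snp_genotypes()] or a TSV path
#' @param microsat [microsat_genotypes()] or a table path
#' @param meta [sample_metadata()] or a CSV path
#' @param n_boot bootstrap replicates for CIs (default 1000)
#' @param seed base seed; every stochastic step derives its own stream from
#'   it
#' @param include_admixture run the admixture scans (default FALSE: they
#'   dominate run time)
#' @param k_range,n_reps admixture scan controls (defaults 1:7 and 20)
#' @param subsample_sizes SNP subset sizes for the resolution experiment
#'   (NULL = skip)
#' @param min_completeness when non-NULL, also rerun the SNP admixture scan
#'   on individuals with at least this completion fraction
#' @return `comparison_report` list; see element names
#' @export
run_comparison <- function(snp, microsat, meta, n_boot = 1000, seed = 1,
                           include_admixture = FALSE, k_range = 1:7,
                           n_reps = 20, subsample_sizes = NULL,
                           min_completeness = NULL) {
  if (is.character(snp)) snp <- read_snp_table(snp)
  if (is.character(microsat)) microsat <- read_microsat_table(microsat)
  if (is.character(meta)) meta <- read_metadata(meta)
  shared <- intersect(individual_ids(snp), individual_ids(microsat))
  assert_that(length(shared) >= 2, "fewer than 2 shared individuals")
  snp <- subset_snps(snp, individuals = match(shared, individual_ids(snp)))
  keep <- match(shared, individual_ids(microsat))
  microsat <- microsat_genotypes(microsat$a1[keep, , drop = FALSE],
                                 microsat$a2[keep, , drop = FALSE])
  meta <- align_metadata(snp, meta)

  tables <- list(snp = population_table(snp, meta),
                 microsat = population_table(microsat, meta))
  overall <- list(
    snp = basic_stats(snp, meta, n_boot = n_boot,
                      seed = child_seed(seed, 11)),
    microsat = basic_stats(microsat, meta, n_boot = n_boot,
                           seed = child_seed(seed, 12)))

  correlations <- do.call(rbind, lapply(
    c("Ho", "Hs", "Fis", "Ar", "Beta"), function(s) {
      ct <- pearson_with_p(tables$snp[[s]], tables$microsat[[s]])
      data.frame(statistic = s, r = ct$r, p = ct$p)
    }))

  fst <- list(snp = pairwise_fst(snp, meta),
              microsat = pairwise_fst(microsat, meta))
  geo <- geographic_distances(meta)
  mantel_markers <- mantel_test(fst$snp, fst$microsat, seed = child_seed(seed, 21),
                                tail = "two.sided")
  ibd <- list(
    snp = ibd_analysis(fst$snp, geo, seed = child_seed(seed, 22)),
    microsat = ibd_analysis(fst$microsat, geo, seed = child_seed(seed, 23)))
  chord <- list(snp = chord_distance_tree(snp, meta),
                microsat = chord_distance_tree(microsat, meta))
  hier <- list(
    snp = hierarchical_fstats(snp, meta, n_boot = n_boot,
                              seed = child_seed(seed, 31)),
    microsat = hierarchical_fstats(microsat, meta, n_boot = n_boot,
                                   seed = child_seed(seed, 32)))
  sexbias <- NULL
  if (sum(meta$sex == "M") >= 2 && sum(meta$sex == "F") >= 2) {
    sexbias <- list(snp = sexbias_test(snp, meta, seed = child_seed(seed, 41)),
                    microsat = sexbias_test(microsat, meta,
                                            seed = child_seed(seed, 42)))
    sexbias$aic_correlation <- pearson_with_p(sexbias$snp$aic$AIc,
                                              sexbias$microsat$aic$AIc)
  }
  pca <- list(snp = genotype_pca(snp), microsat = genotype_pca(microsat))

  admixture <- NULL
  if (include_admixture) {
    admixture <- list(
      snp = admixture_scan(snp, k_range = k_range, n_reps = n_reps,
                           seed = child_seed(seed, 51)),
      microsat_note = "admixture scan runs on biallelic dosages only")
    admixture$snp_k <- select_k(admixture$snp$entropy)
    if (!is.null(subsample_sizes)) {
      admixture$subsample <- snp_subsample_experiment(
        snp, sizes = subsample_sizes, K = admixture$snp_k$k_star,
        n_reps = max(2, n_reps %/% 4), seed = child_seed(seed, 52))
    }
    if (!is.null(min_completeness)) {
      complete <- rowMeans(!is.na(snp$dosage)) >= min_completeness
      if (sum(complete) >= 2) {
        sub <- subset_snps(snp, individuals = which(complete))
        admixture$high_completeness <- admixture_scan(
          sub, k_range = k_range, n_reps = n_reps,
          seed = child_seed(seed, 53))
        admixture$high_completeness_k <-
          select_k(admixture$high_completeness$entropy)
        admixture$high_completeness_n <- sum(complete)
      }
    }
  }

  structure(list(
    n_shared = length(shared),
    tables = tables, overall = overall, correlations = correlations,
    fst = fst, geographic = geo, mantel_markers = mantel_markers,
    ibd = ibd, chord = chord, hierarchical = hier, sexbias = sexbias,
    pca = pca, admixture = admixture,
    missingness = missingness_sensitivity(snp, meta),
    seed = seed, n_boot = n_boot),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: %d shared individuals, %d populations\n",
              x$n_shared, nrow(x$tables$snp)))
  cat(sprintf("  mean pairwise F_ST: SNP %.3f, microsat %.3f\n",
              mean_pairwise_fst(x$fst$snp), mean_pairwise_fst(x$fst$microsat)))
  cat(sprintf("  hierarchical (SNP): Fsc %.3f, Fct %.3f\n",
              x$hierarchical$snp$fstats["Fsc"],
              x$hierarchical$snp$fstats["Fct"]))
  cat(sprintf("  marker Mantel r = %.2f (p = %.3g)\n",
              x$mantel_markers$r, x$mantel_markers$p))
  invisible(x)
}

#' Serialize the numeric core of a report to JSON
#'
#' @param report `comparison_report`
#' @param path output path
#' @export
write_report_json <- function(report, path) {
  core <- list(
    n_shared = report$n_shared,
    seed = report$seed,
    tables = report$tables,
    overall = lapply(report$overall, function(o)
      list(overall = as.list(o$overall), ci = o$ci)),
    correlations = report$correlations,
    mean_pairwise_fst = list(snp = mean_pairwise_fst(report$fst$snp),
                             microsat = mean_pairwise_fst(report$fst$microsat)),
    mantel_markers = report$mantel_markers[c("r", "p")],
    ibd = lapply(report$ibd, function(i) i[c("r", "p", "slope")]),
    hierarchical = lapply(report$hierarchical, function(h)
      list(fstats = as.list(h$fstats), ci = h$ci)),
    missingness = report$missingness[c("correlations", "flag")])
  if (!is.null(report$sexbias)) {
    core$sexbias <- list(
      snp = report$sexbias$snp[c("maic", "t", "p_t", "p_perm")],
      microsat = report$sexbias$microsat[c("maic", "t", "p_t", "p_perm")],
      aic_correlation = report$sexbias$aic_correlation)
  }
  if (!is.null(report$admixture)) {
    core$admixture <- list(k_star = report$admixture$snp_k$k_star,
                           entropy = report$admixture$snp$entropy)
    if (!is.null(report$admixture$subsample)) {
      core$admixture$subsample <- report$admixture$subsample$per_size
    }
  }
  jsonlite::write_json(core, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
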