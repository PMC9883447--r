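# Depth-aware SNP filtering with an auditable ledger. Step order follows the
# calling protocol: (1) repetitive-locus removal (> max SNPs per RAD locus)
# and the per-genotype depth threshold; (2) tri-allelic and unbalanced-
# heterozygote masking, then singleton removal; (3) call-rate; (4) per-locus
# F_IS outlier range. Masking can create singletons, hence the singleton
# check runs after masking. The F_IS outlier screen pools all individuals
# (one-population Nei-Chesser F_IS per locus).

#' Filtering thresholds
#'
#' @param max_snps_per_locus discard all SNPs on RAD loci carrying more than
#'   this many SNPs (repetitive-element guard); default 5
#' @param min_depth minimum total reads per genotype; below it the genotype
#'   is set missing; default 8 (boundary inclusive: depth 8 is kept)
#' @param min_het_allele_fraction heterozygotes whose rarer allele carries
#'   less than this fraction of the reads are set missing; default 0.25
#' @param drop_singletons drop loci whose minor allele is observed exactly
#'   once overall; default TRUE
#' @param min_call_rate minimum fraction of all individuals genotyped at a
#'   locus; default 0.70
#' @param fis_bounds per-locus pooled F_IS acceptance interval; default
#'   c(-0.2, 0.2)
#' @return `filter_config` list
#' @export
filter_config <- function(max_snps_per_locus = 5L, min_depth = 8L,
                          min_het_allele_fraction = 0.25,
                          drop_singletons = TRUE, min_call_rate = 0.70,
                          fis_bounds = c(-0.2, 0.2)) {
  assert_that(min_het_allele_fraction > 0 && min_het_allele_fraction < 0.5,
              "min_het_allele_fraction must be in (0, 0.5)")
  assert_that(min_call_rate > 0 && min_call_rate <= 1,
              "min_call_rate must be in (0, 1]")
  assert_that(length(fis_bounds) == 2 && all(abs(fis_bounds) <= 1) &&
                fis_bounds[1] <= fis_bounds[2],
              "fis_bounds must be an interval within [-1, 1]")
  structure(list(max_snps_per_locus = as.integer(max_snps_per_locus),
                 min_depth = as.integer(min_depth),
                 min_het_allele_fraction = min_het_allele_fraction,
                 drop_singletons = drop_singletons,
                 min_call_rate = min_call_rate,
                 fis_bounds = fis_bounds),
            class = "filter_config")
}

#' SNPs retained under the per-RAD-locus SNP count rule
#'
#' All SNPs sitting on a parent RAD locus with more than
#' `max_snps_per_locus` SNPs are removed together.
#'
#' @param snp_to_radlocus_map named character vector: names are SNP IDs,
#'   values parent RAD locus IDs
#' @param config [filter_config()]
#' @return character vector of retained SNP IDs
#' @export
filter_locus_snp_count <- function(snp_to_radlocus_map, config = filter_config()) {
  assert_that(!is.null(names(snp_to_radlocus_map)) &&
                all(nzchar(names(snp_to_radlocus_map))),
              "map must be named by SNP ID")
  orphan <- is.na(snp_to_radlocus_map) | !nzchar(snp_to_radlocus_map)
  assert_that(!any(orphan), "SNP(s) without parent RAD locus: %s",
              paste(names(snp_to_radlocus_map)[orphan], collapse = ", "))
  per_locus <- table(snp_to_radlocus_map)
  keep_loci <- names(per_locus)[per_locus <= config$max_snps_per_locus]
  names(snp_to_radlocus_map)[snp_to_radlocus_map %in% keep_loci]
}

#' Mask low-quality genotypes using read depths
#'
#' Applies, to non-missing genotypes only: total depth below `min_depth` ->
#' missing; heterozygote with rare-allele read fraction below
#' `min_het_allele_fraction` -> missing (homozygotes unaffected);
#' tri-allelic-flagged genotypes -> missing. Without depths the depth and
#' balance rules are skipped (and reported as such by the pipeline).
#'
#' @param g [snp_genotypes()]
#' @param config [filter_config()]
#' @return list: `genotypes` (masked [snp_genotypes()]), `masked_depth`,
#'   `masked_balance`, `masked_triallelic` (cell counts)
#' @export
mask_low_quality_genotypes <- function(g, config = filter_config()) {
  dosage <- g$dosage
  n_depth <- n_bal <- n_tri <- 0L
  if (!is.null(g$depths)) {
    assert_that(all(g$depths$ref >= 0, na.rm = TRUE) &&
                  all(g$depths$alt >= 0, na.rm = TRUE),
                "negative read depth")
    tot <- g$depths$ref + g$depths$alt
    low <- !is.na(dosage) & tot < config$min_depth
    n_depth <- sum(low)
    dosage[low] <- NA_integer_
    minor <- pmin(g$depths$ref, g$depths$alt)
    unbal <- !is.na(dosage) & dosage == 1L &
      minor / pmax(tot, 1L) < config$min_het_allele_fraction
    n_bal <- sum(unbal)
    dosage[unbal] <- NA_integer_
  }
  if (!is.null(g$tri_allelic)) {
    tri <- !is.na(dosage) & g$tri_allelic
    n_tri <- sum(tri, na.rm = TRUE)
    dosage[tri] <- NA_integer_
  }
  list(genotypes = snp_genotypes(dosage, depths = g$depths,
                                 tri_allelic = g$tri_allelic),
       masked_depth = n_depth, masked_balance = n_bal,
       masked_triallelic = n_tri)
}

# pooled (single-population) per-locus F_IS; NA where gene diversity is 0
locus_fis_pooled <- function(dosage) {
  n <- colSums(!is.na(dosage))
  alt <- colSums(dosage, na.rm = TRUE)
  het <- colSums(dosage == 1L, na.rm = TRUE)
  p <- ifelse(n > 0, alt / (2 * n), NA)
  ho <- ifelse(n > 0, het / n, NA)
  hs <- ifelse(n > 1, n / (n - 1) * (1 - p^2 - (1 - p)^2 - ho / (2 * n)), NA)
  ifelse(!is.na(hs) & hs > 0, 1 - ho / hs, NA)
}

#' Run the full SNP filtering pipeline
#'
#' @param g [snp_genotypes()]
#' @param config [filter_config()]
#' @param snp_to_radlocus_map optional named map of SNP ID -> RAD locus ID;
#'   when absent the SNP-count step is skipped and recorded as skipped
#' @return list: `genotypes` (filtered [snp_genotypes()]), `report` (data
#'   frame: step, cells_masked, loci_dropped, loci_remaining) with attributes
#'   `initial_dim` and `final_dim`
#' @export
run_filter_pipeline <- function(g, config = filter_config(),
                                snp_to_radlocus_map = NULL) {
  steps <- list()
  initial_dim <- dim(g$dosage)
  log_step <- function(step, masked, dropped, g) {
    steps[[length(steps) + 1]] <<- data.frame(
      step = step, cells_masked = masked, loci_dropped = dropped,
      loci_remaining = ncol(g$dosage))
    if (ncol(g$dosage) == 0) {
      stopf("filtering step '%s' removed every locus", step)
    }
  }

  # (1a) repetitive RAD loci
  if (!is.null(snp_to_radlocus_map)) {
    keep <- filter_locus_snp_count(snp_to_radlocus_map, config)
    keep_idx <- colnames(g$dosage) %in% keep |
      !(colnames(g$dosage) %in% names(snp_to_radlocus_map))
    dropped <- sum(!keep_idx)
    g <- subset_snps(g, loci = which(keep_idx))
    log_step("snp_count_per_rad_locus", 0L, dropped, g)
  } else {
    log_step("snp_count_per_rad_locus (skipped: no map)", 0L, 0L, g)
  }

  # (1b) depth + (2a) balance/tri-allelic masks
  if (is.null(g$depths)) {
    log_step("depth_mask (skipped: no depths)", 0L, 0L, g)
    if (is.null(g$tri_allelic)) {
      log_step("triallelic_balance_mask (skipped: no depths)", 0L, 0L, g)
    } else {
      mk <- mask_low_quality_genotypes(g, config)
      g <- mk$genotypes
      log_step("triallelic_balance_mask", mk$masked_triallelic, 0L, g)
    }
  } else {
    tot <- g$depths$ref + g$depths$alt
    low <- !is.na(g$dosage) & tot < config$min_depth
    d <- g$dosage
    d[low] <- NA_integer_
    g <- snp_genotypes(d, depths = g$depths, tri_allelic = g$tri_allelic)
    log_step("depth_mask", sum(low), 0L, g)
    mk <- mask_low_quality_genotypes(
      snp_genotypes(g$dosage, depths = g$depths, tri_allelic = g$tri_allelic),
      config)
    g <- mk$genotypes
    log_step("triallelic_balance_mask", mk$masked_balance + mk$masked_triallelic,
             0L, g)
  }

  # (2b) singletons: minor allele observed exactly once overall
  if (config$drop_singletons) {
    alt <- colSums(g$dosage, na.rm = TRUE)
    n <- colSums(!is.na(g$dosage))
    minor <- pmin(alt, 2 * n - alt)
    keep <- minor != 1L
    dropped <- sum(!keep)
    g <- subset_snps(g, loci = which(keep))
    log_step("singleton_removal", 0L, dropped, g)
  } else {
    log_step("singleton_removal (skipped)", 0L, 0L, g)
  }

  # (3) call rate over all individuals in the matrix
  call_rate <- colMeans(!is.na(g$dosage))
  keep <- call_rate >= config$min_call_rate
  dropped <- sum(!keep)
  g <- subset_snps(g, loci = which(keep))
  log_step("call_rate", 0L, dropped, g)

  # (4) pooled per-locus F_IS outlier range (undefined F_IS retained)
  fis <- locus_fis_pooled(g$dosage)
  keep <- is.na(fis) | (fis >= config$fis_bounds[1] & fis <= config$fis_bounds[2])
  dropped <- sum(!keep)
  g <- subset_snps(g, loci = which(keep))
  log_step("fis_outlier", 0L, dropped, g)

  report <- do.call(rbind, steps)
  attr(report, "initial_dim") <- initial_dim
  attr(report, "final_dim") <- dim(g$dosage)
  list(genotypes = g, report = report)
}
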