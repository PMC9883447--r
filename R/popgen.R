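# Diversity and differentiation estimators in the Nei-Chesser / Weir
# conventions. Per-locus sample-size corrections:
#   H_S = n/(n-1) * (1 - sum(p^2) - H_O/(2n))           (within population)
#   H_T = 1 - sum(pbar^2) + HSbar/(nh * s) - HObar/(2 * nh * s)
# with pbar the unweighted mean frequency across the s populations observed
# at the locus and nh their harmonic mean sample size. Multi-locus F's are
# ratios of sums over loci, never means of per-locus ratios.

# per-locus, per-pop Ho/Hs plus per-locus Ht; the engine under basic_stats
# and the locus-wise F_IS used by the filtering rules
locus_diversity <- function(lc, pops) {
  n_loci <- length(lc)
  ho <- hs <- matrix(NA_real_, length(pops), n_loci, dimnames = list(pops, NULL))
  ht <- numeric(n_loci)
  for (j in seq_len(n_loci)) {
    x <- lc[[j]]
    tot <- rowSums(x$counts)
    obs <- x$n > 0
    p <- x$counts / ifelse(tot > 0, tot, NA)
    ho_j <- ifelse(obs, x$het / x$n, NA)
    sp2 <- rowSums(p^2)
    hs_j <- ifelse(obs & x$n > 1,
                   x$n / (x$n - 1) * (1 - sp2 - ho_j / (2 * x$n)),
                   NA)
    ho[, j] <- ho_j
    hs[, j] <- hs_j
    s <- sum(obs & x$n > 1)
    if (s >= 2) {
      use <- obs & x$n > 1
      pbar <- colMeans(p[use, , drop = FALSE])
      nh <- harmonic_mean(x$n[use])
      ht[j] <- 1 - sum(pbar^2) +
        mean(hs_j[use]) / (nh * s) - mean(ho_j[use]) / (2 * nh * s)
    } else {
      ht[j] <- NA_real_
    }
  }
  list(ho = ho, hs = hs, ht = ht)
}

#' Basic diversity statistics (H_O, H_S, F_IS, h_T)
#'
#' Per population: observed heterozygosity, Nei-Chesser gene diversity and
#' F_IS = 1 - H_O/H_S, each averaged over the loci observed in that
#' population. Overall: loci-wise means of the per-locus population averages,
#' the total gene diversity h_T from mean-across-population frequencies with
#' the matching small-sample correction, overall F_IS as a ratio of sums, and
#' the Nei-style overall F_ST = (h_T - mean H_S)/h_T. Monomorphic data yield
#' F's of `NA` (undefined), never 0.
#'
#' @inheritParams allele_frequencies
#' @param n_boot bootstrap replicates over loci for 95% CIs (0 = none)
#' @param seed RNG seed for the bootstrap
#' @return list with `per_population` (data frame: population, Ho, Hs, Fis),
#'   `per_locus` (matrices), `overall` (named vector Ho, Hs, Ht, Fis, Fst)
#'   and, when bootstrapped, `ci` (rows Ho, Hs, Ht, Fis, Fst).
#' @export
basic_stats <- function(g, meta, n_boot = 0, seed = NULL) {
  meta <- align_metadata(g, meta)
  pops <- unique(meta$population)
  lc <- locus_count_list(g, meta$population, pops)
  ld <- locus_diversity(lc, pops)
  per_pop <- data.frame(
    population = pops,
    Ho = rowMeans(ld$ho, na.rm = TRUE),
    Hs = rowMeans(ld$hs, na.rm = TRUE),
    row.names = NULL)
  per_pop$Fis <- 1 - per_pop$Ho / ifelse(per_pop$Hs > 0, per_pop$Hs, NA)
  overall_fn <- function(idx) {
    ho_l <- colMeans(ld$ho[, idx, drop = FALSE], na.rm = TRUE)
    hs_l <- colMeans(ld$hs[, idx, drop = FALSE], na.rm = TRUE)
    ht_l <- ld$ht[idx]
    ho <- mean(ho_l, na.rm = TRUE)
    hs <- mean(hs_l, na.rm = TRUE)
    ht <- mean(ht_l, na.rm = TRUE)
    c(Ho = ho, Hs = hs, Ht = ht,
      Fis = if (isTRUE(hs > 0)) 1 - ho / hs else NA_real_,
      Fst = if (isTRUE(ht > 0)) (ht - hs) / ht else NA_real_)
  }
  out <- list(per_population = per_pop,
              per_locus = ld,
              overall = overall_fn(seq_along(lc)))
  if (n_boot > 0) {
    bs <- bootstrap_loci(overall_fn, length(lc), n_boot, seed)
    out$ci <- bs
  }
  out
}

#' Gene-diversity confidence envelope given allele frequency
#'
#' The diagnostic band used to flag outlier loci when plotting per-allele
#' heterozygosity against frequency: center `2p(1-p)(1-f_IT)` and half-width
#' `2*sqrt(2p(1-p)(1+f_IT)/N)`, exactly as printed in the source framework.
#' A variance-derivation variant with `(1-f_IT)` inside the radical is
#' available via `radical_sign`.
#'
#' @param p allele frequency (vectorized)
#' @param f_it global heterozygote deficit F_IT
#' @param n sample size (individuals)
#' @param radical_sign `"plus"` (as printed; default) or `"minus"`
#' @return data frame with `center`, `lower`, `upper`
#' @export
hs_envelope_bounds <- function(p, f_it, n, radical_sign = c("plus", "minus")) {
  radical_sign <- match.arg(radical_sign)
  assert_that(all(p >= 0 & p <= 1), "allele frequency outside [0, 1]")
  assert_that(all(n >= 1), "sample size must be >= 1")
  center <- 2 * p * (1 - p) * (1 - f_it)
  f_in <- if (radical_sign == "plus") 1 + f_it else 1 - f_it
  half <- 2 * sqrt(2 * p * (1 - p) * f_in / n)
  data.frame(center = center, lower = center - half, upper = center + half)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a standardized draw of `g_copies`
#' allele copies (hypergeometric rarefaction),
#' `A_R = sum_i [1 - choose(N - N_i, g)/choose(N, g)]`, per locus, averaged
#' over loci per population.
#'
#' @inheritParams allele_frequencies
#' @param g_copies allele copies to rarefy to; default `2 * min` non-missing
#'   genotypes over populations at each locus (locus-specific)
#' @return data frame: population, Ar
#' @export
allelic_richness <- function(g, meta, g_copies = NULL) {
  if (!is.null(g_copies)) {
    assert_that(g_copies >= 2, "g_copies must be >= 2")
  }
  meta <- align_metadata(g, meta)
  pops <- unique(meta$population)
  lc <- locus_count_list(g, meta$population, pops)
  ar <- matrix(NA_real_, length(pops), length(lc))
  for (j in seq_along(lc)) {
    x <- lc[[j]]
    obs <- x$n > 0
    gj <- g_copies %||% (2 * min(x$n[obs]))
    if (gj < 1) next
    for (pidx in which(obs)) {
      cnt <- x$counts[pidx, ]
      tot <- sum(cnt)
      if (tot < gj) next  # cannot rarefy below requested copies
      ar[pidx, j] <- sum(1 - exp(lchoose(tot - cnt, gj) - lchoose(tot, gj)))
    }
  }
  data.frame(population = pops, Ar = rowMeans(ar, na.rm = TRUE))
}

#' Population-specific F_ST (Beta) by allele matching
#'
#' For each population, Beta = (M_w - M_b)/(1 - M_b) where M_w is the
#' within-population probability that two distinct allele copies match
#' (`sum_a N_a (N_a - 1) / (N (N - 1))`) and M_b the mean between-population
#' matching (`sum_a p_a q_a`) over all population pairs at the locus.
#' Multi-locus values are ratios of sums over loci.
#'
#' @inheritParams allele_frequencies
#' @return list: `per_population` (data frame population, Beta), `overall`
#'   (mean of per-population values), and per-locus numerator/denominator
#'   matrices used by the bootstrap
#' @export
population_specific_fst <- function(g, meta) {
  meta <- align_metadata(g, meta)
  pops <- unique(meta$population)
  assert_that(length(pops) >= 2, "Beta needs at least 2 populations")
  lc <- locus_count_list(g, meta$population, pops)
  comp <- beta_components(lc, pops)
  beta <- rowSums(comp$num, na.rm = TRUE) / rowSums(comp$den, na.rm = TRUE)
  list(per_population = data.frame(population = pops, Beta = beta),
       overall = mean(beta, na.rm = TRUE),
       components = comp)
}

# per-locus matching components: num = M_w - Mb_bar, den = 1 - Mb_bar
beta_components <- function(lc, pops) {
  num <- den <- matrix(NA_real_, length(pops), length(lc),
                       dimnames = list(pops, NULL))
  for (j in seq_along(lc)) {
    x <- lc[[j]]
    tot <- rowSums(x$counts)
    use <- tot > 1
    if (sum(use) < 2) next
    p <- x$counts[use, , drop = FALSE] / tot[use]
    mw <- rowSums(x$counts[use, , drop = FALSE] *
                    (x$counts[use, , drop = FALSE] - 1)) /
      (tot[use] * (tot[use] - 1))
    pp <- p %*% t(p)           # pairwise between-pop matching
    diag(pp) <- NA
    mb <- mean(pp[upper.tri(pp)])
    num[use, j] <- mw - mb
    den[use, j] <- 1 - mb
  }
  list(num = num, den = den)
}

# percentile bootstrap over loci of any vector-valued statistic of a locus
# index set; deterministic given seed
bootstrap_loci <- function(stat_fn, n_loci, n_boot, seed = NULL,
                           probs = c(0.025, 0.975)) {
  assert_that(n_boot >= 2, "n_boot must be >= 2")
  if (n_loci < 20) warnf("bootstrap over only %d loci; CIs will be unstable",
                         n_loci)
  est <- stat_fn(seq_len(n_loci))
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(b) stat_fn(sample.int(n_loci, n_loci, replace = TRUE)),
           est)
  })
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1,
                                         dimnames = list(names(est) %||% "stat"))
  qs <- apply(reps, 1, stats::quantile, probs = probs, na.rm = TRUE, names = FALSE)
  data.frame(statistic = rownames(reps) %||% names(est),
             estimate = as.numeric(est),
             lower = qs[1, ], upper = qs[2, ], row.names = NULL)
}

#' Bootstrap confidence interval for a multi-locus statistic
#'
#' Loci are resampled with replacement and the statistic recomputed as a
#' ratio of summed per-locus variance components per replicate; percentile
#' 2.5%/97.5% bounds.
#'
#' @inheritParams allele_frequencies
#' @param statistic one of `"fst"` (overall Weir-Cockerham theta), `"fis"`
#'   (overall, Nei-Chesser), `"ho"`, `"hs"`, `"ht"` (means over loci),
#'   `"beta"` (per population)
#' @param n_boot replicates (default 1000)
#' @param seed RNG seed (recorded in the result)
#' @return data frame with columns statistic, estimate, lower, upper;
#'   attribute `seed`
#' @export
bootstrap_ci <- function(g, meta, statistic = c("fst", "fis", "ho", "hs",
                                                "ht", "beta"),
                         n_boot = 1000, seed = NULL) {
  statistic <- match.arg(statistic)
  meta <- align_metadata(g, meta)
  pops <- unique(meta$population)
  lc <- locus_count_list(g, meta$population, pops)
  n_loci <- length(lc)
  fn <- switch(
    statistic,
    fst = {
      comp <- wc_locus_components(lc, pops)
      function(idx) c(fst = sum(comp$a[idx]) /
                        sum(comp$a[idx] + comp$b[idx] + comp$c[idx]))
    },
    fis = {
      ld <- locus_diversity(lc, pops)
      function(idx) {
        ho <- mean(colMeans(ld$ho[, idx, drop = FALSE], na.rm = TRUE), na.rm = TRUE)
        hs <- mean(colMeans(ld$hs[, idx, drop = FALSE], na.rm = TRUE), na.rm = TRUE)
        c(fis = 1 - ho / hs)
      }
    },
    ho = {
      ld <- locus_diversity(lc, pops)
      function(idx) c(ho = mean(colMeans(ld$ho[, idx, drop = FALSE],
                                         na.rm = TRUE), na.rm = TRUE))
    },
    hs = {
      ld <- locus_diversity(lc, pops)
      function(idx) c(hs = mean(colMeans(ld$hs[, idx, drop = FALSE],
                                         na.rm = TRUE), na.rm = TRUE))
    },
    ht = {
      ld <- locus_diversity(lc, pops)
      function(idx) c(ht = mean(ld$ht[idx], na.rm = TRUE))
    },
    beta = {
      comp <- beta_components(lc, pops)
      function(idx) {
        v <- rowSums(comp$num[, idx, drop = FALSE], na.rm = TRUE) /
          rowSums(comp$den[, idx, drop = FALSE], na.rm = TRUE)
        names(v) <- paste0("beta.", pops)
        v
      }
    })
  out <- bootstrap_loci(fn, n_loci, n_boot, seed)
  attr(out, "seed") <- seed
  out
}
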