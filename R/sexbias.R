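# Sex-biased dispersal via corrected assignment indices. An individual's
# assignment index AI is the log10 probability of its multilocus genotype in
# its sampled population under Hardy-Weinberg, with leave-one-out allele
# frequencies (the focal individual's alleles removed from the counts) and a
# 1/(2n) floor for alleles unobserved after removal — the private alleles of
# immigrants are the very signal sought, so they must not produce -Inf.
# AIc centers AI within each population; members of the dispersing sex carry
# genotypes less typical of where they were caught, lowering their mean AIc.

# per-individual assignment index, SNP fast path
ai_snp <- function(dosage, pop) {
  pf <- factor(pop, levels = unique(pop))
  sc <- snp_pop_counts(dosage, pf)
  alt_p <- sc$alt[as.integer(pf), , drop = FALSE]
  n_p <- sc$n[as.integer(pf), , drop = FALSE]
  obs <- !is.na(dosage)
  x <- dosage
  x[!obs] <- 0L
  n_loo <- n_p - obs
  p_loo <- (alt_p - x) / pmax(2 * n_loo, 1)
  floor_p <- 1 / pmax(2 * n_loo, 1)
  p_loo <- pmin(pmax(p_loo, floor_p), 1 - floor_p)
  q_loo <- 1 - p_loo
  lp <- ifelse(x == 2L, 2 * log10(p_loo),
               ifelse(x == 1L, log10(2) + log10(p_loo) + log10(q_loo),
                      2 * log10(q_loo)))
  lp[!obs | n_loo < 1] <- 0
  rowSums(lp)
}

# generic path (microsatellites): per-locus allele counts, LOO correction
ai_multiallelic <- function(g, pop) {
  pops <- unique(pop)
  pf <- factor(pop, levels = pops)
  ai <- numeric(nrow(g$a1))
  for (j in seq_len(ncol(g$a1))) {
    a1 <- g$a1[, j]; a2 <- g$a2[, j]
    ok <- !is.na(a1)
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    if (length(alleles) == 0) next
    cnt <- matrix(0, length(pops), length(alleles),
                  dimnames = list(pops, as.character(alleles)))
    for (a in seq_along(alleles)) {
      xa <- (a1 == alleles[a]) + (a2 == alleles[a])
      s <- rowsum(ifelse(is.na(xa), 0, xa), pf)
      cnt[rownames(s), a] <- s
    }
    n <- rowsum(as.numeric(ok), pf)[, 1]
    for (i in which(ok)) {
      p <- pops == pop[i]
      n_loo <- n[p] - 1
      if (n_loo < 1) next
      floor_p <- 1 / (2 * n_loo)
      cl <- cnt[p, ]
      cl[as.character(a1[i])] <- cl[as.character(a1[i])] - 1
      cl[as.character(a2[i])] <- cl[as.character(a2[i])] - 1
      pl <- pmax(cl / (2 * n_loo), floor_p)
      if (a1[i] == a2[i]) {
        ai[i] <- ai[i] + 2 * log10(pl[as.character(a1[i])])
      } else {
        ai[i] <- ai[i] + log10(2) + log10(pl[as.character(a1[i])]) +
          log10(pl[as.character(a2[i])])
      }
    }
  }
  ai
}

#' Test for sex-biased dispersal (corrected assignment index)
#'
#' Computes per-individual AIc (assignment index centered within its
#' population; AIc sums to ~0 within each population by construction), then
#' compares males against females pooled across populations with a Welch
#' t-test and a within-population sex-label permutation test.
#'
#' @inheritParams allele_frequencies
#' @param n_perm permutations for the randomization p-value (default 999)
#' @param seed RNG seed for the permutations
#' @return list: `maic` (named vector: mean AIc by sex), `t`, `p_t` (Welch),
#'   `p_perm`, `aic` (per-individual data frame), `degenerate` flag (TRUE
#'   when AIc has no variance)
#' @export
sexbias_test <- function(g, meta, n_perm = 999, seed = NULL) {
  meta <- align_metadata(g, meta)
  known <- meta$sex %in% c("M", "F")
  assert_that(sum(meta$sex == "M") >= 2 && sum(meta$sex == "F") >= 2,
              "need >= 2 individuals of each known sex")
  ai <- if (is_snp(g)) ai_snp(g$dosage, meta$population)
        else ai_multiallelic(g, meta$population)
  aic <- ai - stats::ave(ai, meta$population)
  df <- data.frame(individual = meta$individual,
                   population = meta$population, sex = meta$sex,
                   AI = ai, AIc = aic)
  m <- aic[known & meta$sex == "M"]
  f <- aic[known & meta$sex == "F"]
  maic <- c(M = mean(m), F = mean(f))
  degenerate <- stats::sd(c(m, f)) == 0 ||
    (stats::sd(m) == 0 && stats::sd(f) == 0)
  if (degenerate) {
    return(list(maic = maic, t = 0, p_t = NA_real_, p_perm = NA_real_,
                aic = df, degenerate = TRUE))
  }
  tt <- stats::t.test(m, f)
  obs_diff <- maic["M"] - maic["F"]
  perm_diff <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      sex_p <- meta$sex
      for (p in unique(meta$population)) {
        in_p <- which(meta$population == p)
        sex_p[in_p] <- meta$sex[in_p][sample.int(length(in_p))]
      }
      kp <- sex_p %in% c("M", "F")
      mean(aic[kp & sex_p == "M"]) - mean(aic[kp & sex_p == "F"])
    }, numeric(1))
  })
  p_perm <- (sum(abs(perm_diff) >= abs(obs_diff)) + 1) / (n_perm + 1)
  list(maic = maic, t = unname(tt$statistic), p_t = tt$p.value,
       p_perm = p_perm, aic = df, degenerate = FALSE)
}
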