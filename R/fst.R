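# Weir-Cockerham (1984) theta and its hierarchical extension. Pairwise theta
# is computed from the explicit a/b/c moment formulas; the nested
# country/population/individual/gamete decomposition is computed by an
# independent route (Henderson method-of-moments on gamete allele
# indicators), and the two are required to agree when the hierarchy
# degenerates to a single level.

# WC84 variance components for one locus across r >= 2 populations, summed
# over alleles. counts: pops x alleles; n: genotypes per pop; het_by_allele:
# pops x alleles heterozygote-carrier counts.
wc_one_locus <- function(counts, n, het_by_allele) {
  use <- n > 0
  r <- sum(use)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  n <- n[use]
  counts <- counts[use, , drop = FALSE]
  het_by_allele <- het_by_allele[use, , drop = FALSE]
  nbar <- mean(n)
  if (nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  p <- counts / (2 * n)
  abc <- c(a = 0, b = 0, c = 0)
  for (al in seq_len(ncol(counts))) {
    pa <- p[, al]
    pbar <- sum(n * pa) / (r * nbar)
    s2 <- sum(n * (pa - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(het_by_allele[, al]) / (r * nbar)
    inner <- pbar * (1 - pbar) - (r - 1) / r * s2
    a <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    abc <- abc + c(a = a, b = b, c = cc)
  }
  abc
}

# per-locus WC components over all populations (generic path)
wc_locus_components <- function(lc, pops) {
  a <- b <- cc <- numeric(length(lc))
  for (j in seq_along(lc)) {
    x <- lc[[j]]
    v <- wc_one_locus(x$counts, x$n, x$het_by_allele)
    a[j] <- v["a"]; b[j] <- v["b"]; cc[j] <- v["c"]
  }
  list(a = a, b = b, c = cc)
}

# vectorized biallelic WC components for one population pair across loci
wc_pair_snp <- function(alt, n, het, i, j) {
  n1 <- n[i, ]; n2 <- n[j, ]
  ok <- n1 > 0 & n2 > 0 & (n1 + n2) / 2 > 1
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  p1 <- alt[i, ] / (2 * n1); p2 <- alt[j, ] / (2 * n2)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (het[i, ] + het[j, ]) / (r * nbar)
  inner <- pbar * (1 - pbar) - (r - 1) / r * s2
  a <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA; b[!ok] <- NA; cc[!ok] <- NA
  list(a = 2 * a, b = 2 * b, c = 2 * cc)  # both alleles of each biallelic locus
}

#' Pairwise F_ST between populations (Weir-Cockerham theta)
#'
#' Theta per population pair, with variance components summed over loci (and
#' over alleles for multiallelic loci). Slightly negative estimates are kept
#' as computed. A pair with no co-observed polymorphic locus is `NA`.
#'
#' @inheritParams allele_frequencies
#' @return `dist_matrix`: list with `labels`, symmetric `matrix`, `kind =
#'   "fst"`
#' @export
pairwise_fst <- function(g, meta) {
  meta <- align_metadata(g, meta)
  pops <- unique(meta$population)
  assert_that(length(pops) >= 2, "pairwise F_ST needs at least 2 populations")
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  if (is_snp(g)) {
    sc <- snp_pop_counts(g$dosage, factor(meta$population, levels = pops))
    for (i in seq_along(pops)[-length(pops)]) {
      for (j in seq((i + 1), length(pops))) {
        comp <- wc_pair_snp(sc$alt, sc$n, sc$het, i, j)
        den <- sum(comp$a + comp$b + comp$c, na.rm = TRUE)
        m[i, j] <- m[j, i] <- if (den > 0) {
          sum(comp$a, na.rm = TRUE) / den
        } else NA_real_
      }
    }
  } else {
    lc <- locus_count_list(g, meta$population, pops)
    for (i in seq_along(pops)[-length(pops)]) {
      for (j in seq((i + 1), length(pops))) {
        num <- den <- 0
        for (x in lc) {
          sub_n <- x$n[c(i, j)]
          v <- wc_one_locus(x$counts[c(i, j), , drop = FALSE], sub_n,
                            x$het_by_allele[c(i, j), , drop = FALSE])
          if (!is.na(v["a"])) {
            num <- num + v["a"]
            den <- den + sum(v)
          }
        }
        m[i, j] <- m[j, i] <- if (den > 0) num / den else NA_real_
      }
    }
  }
  dist_matrix(m, kind = "fst")
}

#' Mean pairwise F_ST
#' @param fst a `dist_matrix` from [pairwise_fst()]
#' @return mean of the off-diagonal pairs
#' @export
mean_pairwise_fst <- function(fst) {
  mean(fst$matrix[upper.tri(fst$matrix)], na.rm = TRUE)
}

# allele-indicator matrix with per-column locus assignment
indicator_columns <- function(g) {
  x <- allele_dosage_matrix(g)
  locus <- if (is_snp(g)) locus_ids(g) else sub("\\.[^.]+$", "", colnames(x))
  list(x = x, locus = locus, double = is_snp(g))
}

#' Hierarchical F-statistics (countries / populations / individuals)
#'
#' Method-of-moments nested random-effects decomposition of gamete allele
#' indicators into country, population-within-country, individual-within-
#' population and within-individual components, handling unequal and missing
#' sample sizes exactly. `F_CT = s2_C / s2_tot`,
#' `F_SC = s2_P / (s2_tot - s2_C)`, `F_ST = (s2_C + s2_P) / s2_tot`,
#' `F_IS = s2_I / (s2_I + s2_G)`; components are summed over loci and alleles
#' before taking ratios. The identity `(1 - F_SC)(1 - F_CT) = 1 - F_ST` holds
#' by construction.
#'
#' @inheritParams allele_frequencies
#' @param n_boot bootstrap replicates over loci for 95% CIs (0 = none)
#' @param seed RNG seed for the bootstrap
#' @return list with `components` (summed variance components), `fstats`
#'   (named vector Fst, Fsc, Fct, Fis) and optional `ci`
#' @export
hierarchical_fstats <- function(g, meta, n_boot = 0, seed = NULL) {
  meta <- align_metadata(g, meta)
  assert_that(length(unique(meta$country)) >= 2,
              "only one country: use pairwise_fst()/basic_stats() instead")
  ic <- indicator_columns(g)
  D <- ic$x
  obs <- !is.na(D)
  D0 <- D; D0[!obs] <- 0L
  pop <- factor(meta$population, levels = unique(meta$population))
  cty <- factor(meta$country, levels = unique(meta$country))

  T_col <- colSums(D0)
  u_obs <- T_col
  u_ind <- colSums(D0^2) / 2
  P <- rowsum(D0, pop); n_pc <- rowsum(obs + 0L, pop)
  Cc <- rowsum(D0, cty); n_cc <- rowsum(obs + 0L, cty)
  safe_div <- function(num, den) ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
  u_pop <- colSums(safe_div(P^2, 2 * n_pc))
  u_cty <- colSums(safe_div(Cc^2, 2 * n_cc))
  n_col <- colSums(obs)
  u_tot <- ifelse(n_col > 0, T_col^2 / (2 * n_col), 0)

  ss_g <- u_obs - u_ind
  ss_i <- u_ind - u_pop
  ss_p <- u_pop - u_cty
  ss_c <- u_cty - u_tot

  npop <- colSums(n_pc > 0)
  ncty <- colSums(n_cc > 0)
  # expand pop -> country mapping for the K1 coefficient
  pop_cty <- cty[match(levels(pop), as.character(pop))]
  n_cc_by_pop <- n_cc[as.integer(pop_cty), , drop = FALSE]
  K1 <- colSums(safe_div((2 * n_pc)^2, 2 * n_cc_by_pop))
  K2 <- safe_div(colSums((2 * n_pc)^2), 2 * n_col)
  K3 <- safe_div(colSums((2 * n_cc)^2), 2 * n_col)

  sig_g <- ifelse(n_col > 0, ss_g / n_col, NA)
  den_i <- 2 * n_col - 2 * npop
  sig_i <- ifelse(den_i > 0, (ss_i - (n_col - npop) * sig_g) / den_i, 0)
  den_p <- 2 * n_col - K1
  sig_p <- ifelse(abs(den_p) > 1e-9,
                  (ss_p - (npop - ncty) * sig_g - (2 * npop - 2 * ncty) * sig_i) /
                    ifelse(abs(den_p) > 1e-9, den_p, 1),
                  0)
  den_c <- 2 * n_col - K3
  sig_c <- ifelse(abs(den_c) > 1e-9,
                  (ss_c - (ncty - 1) * sig_g - (2 * ncty - 2) * sig_i -
                     (K1 - K2) * sig_p) /
                    ifelse(abs(den_c) > 1e-9, den_c, 1),
                  0)
  keep <- !is.na(sig_g) & n_col > 1 & npop >= 1
  mult <- if (ic$double) 2 else 1
  comp_cols <- rbind(country = sig_c, population = sig_p,
                     individual = sig_i, gamete = sig_g) * mult
  comp_cols[, !keep] <- NA

  # per-locus sums for the bootstrap
  loci <- unique(ic$locus)
  lf <- factor(ic$locus, levels = loci)
  comp_by_locus <- t(rowsum(t(ifelse(is.na(comp_cols), 0, comp_cols)),
                            lf))
  fstats_fn <- function(idx) {
    s <- rowSums(comp_by_locus[, idx, drop = FALSE])
    tot <- sum(s)
    c(Fst = (s["country"] + s["population"]) / tot,
      Fsc = s["population"] / (tot - s["country"]),
      Fct = s["country"] / tot,
      Fis = s["individual"] / (s["individual"] + s["gamete"])) |>
      stats::setNames(c("Fst", "Fsc", "Fct", "Fis"))
  }
  out <- list(components = rowSums(comp_by_locus),
              fstats = fstats_fn(seq_along(loci)))
  if (n_boot > 0) out$ci <- bootstrap_loci(fstats_fn, length(loci), n_boot, seed)
  out
}
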