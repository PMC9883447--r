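# Allele-count abstraction: every estimator consumes per-population allele
# counts, observed-heterozygote counts and sample sizes, so biallelic SNPs and
# multiallelic microsatellites share one code path (plus vectorized SNP fast
# paths where the locus count is large).

#' Per-population allele frequencies
#'
#' Frequencies from allele counts among non-missing genotypes, identical code
#' path for biallelic and multiallelic data. A (population, locus) cell with
#' no non-missing genotype is flagged absent (`NaN` frequencies, `n = 0`) and
#' skipped by downstream statistics (pairwise-complete convention).
#'
#' @param g [snp_genotypes()] or [microsat_genotypes()]
#' @param meta [sample_metadata()]
#' @return `allele_freq_table`: list with `populations`, `loci`, `freq` (per
#'   locus: populations x alleles frequency matrix), `counts` (allele copies),
#'   `het` (observed heterozygote counts), `n` (populations x loci non-missing
#'   genotype counts), `n_harmonic` (per-locus harmonic mean of `n` over
#'   populations with data).
#' @export
allele_frequencies <- function(g, meta) {
  meta <- align_metadata(g, meta)
  pops <- unique(meta$population)
  empty <- setdiff(unique(meta$population), meta$population)
  assert_that(length(empty) == 0, "population(s) with zero individuals: %s",
              paste(empty, collapse = ", "))
  lc <- locus_count_list(g, meta$population, pops)
  n <- vapply(lc, `[[`, numeric(length(pops)), "n")
  if (is.null(dim(n))) n <- matrix(n, nrow = length(pops))
  dimnames(n) <- list(pops, locus_ids(g))
  freq <- lapply(lc, function(x) {
    f <- x$counts / rowSums(x$counts)
    f
  })
  structure(list(populations = pops, loci = locus_ids(g), freq = freq,
                 counts = lapply(lc, `[[`, "counts"),
                 het = vapply(lc, `[[`, numeric(length(pops)), "het") |>
                   matrix(nrow = length(pops), dimnames = list(pops, locus_ids(g))),
                 n = n,
                 n_harmonic = apply(n, 2, harmonic_mean)),
            class = "allele_freq_table")
}

# generic per-locus counts: list per locus of
#   counts: pops x alleles matrix of allele copies
#   het:    per-pop observed heterozygote count
#   n:      per-pop non-missing genotype count
locus_count_list <- function(g, pop_of_ind, pops) {
  pf <- factor(pop_of_ind, levels = pops)
  if (is_snp(g)) {
    sc <- snp_pop_counts(g$dosage, pf)
    lapply(seq_along(locus_ids(g)), function(j) {
      cnt <- cbind(ref = 2 * sc$n[, j] - sc$alt[, j], alt = sc$alt[, j])
      rownames(cnt) <- pops
      list(counts = cnt, het = sc$het[, j], n = sc$n[, j],
           het_by_allele = cbind(ref = sc$het[, j], alt = sc$het[, j]))
    })
  } else {
    lapply(seq_len(ncol(g$a1)), function(j) {
      a1 <- g$a1[, j]
      a2 <- g$a2[, j]
      ok <- !is.na(a1)
      alleles <- sort(unique(c(a1[ok], a2[ok])))
      if (!length(alleles)) alleles <- NA_integer_
      cnt <- matrix(0, length(pops), length(alleles),
                    dimnames = list(pops, as.character(alleles)))
      hba <- cnt
      for (a in seq_along(alleles)) {
        x <- (a1 == alleles[a]) + (a2 == alleles[a])
        s <- rowsum(ifelse(is.na(x), 0, x), pf)
        cnt[rownames(s), a] <- s
        # heterozygous for allele a = exactly one copy
        h <- rowsum(as.numeric(!is.na(x) & x == 1), pf)
        hba[rownames(h), a] <- h
      }
      het <- rowsum(as.numeric(ok & a1 != a2), pf)
      n <- rowsum(as.numeric(ok), pf)
      list(counts = cnt, het = structure(het[, 1], names = rownames(het)),
           n = structure(n[, 1], names = rownames(n)), het_by_allele = hba)
    })
  }
}

# vectorized SNP tallies: pops x loci matrices of alt-allele copies,
# heterozygote counts and non-missing genotype counts
snp_pop_counts <- function(dosage, pop_factor) {
  x <- dosage
  x[is.na(x)] <- 0L
  alt <- rowsum(x, pop_factor)
  het <- rowsum(((!is.na(dosage)) & dosage == 1L) + 0L, pop_factor)
  n <- rowsum((!is.na(dosage)) + 0L, pop_factor)
  list(alt = alt, het = het, n = n)
}

# per-individual allele "dosage" expansion for a generic genotype object:
# columns are (locus, allele) pairs; used by PCA and chord-style machinery
allele_dosage_matrix <- function(g) {
  if (is_snp(g)) {
    m <- g$dosage
    colnames(m) <- paste0(colnames(m), ".alt")
    return(m)
  }
  cols <- list()
  for (j in seq_len(ncol(g$a1))) {
    a1 <- g$a1[, j]
    a2 <- g$a2[, j]
    alleles <- sort(unique(stats::na.omit(c(a1, a2))))
    for (a in alleles) {
      v <- (a1 == a) + (a2 == a)
      cols[[paste0(colnames(g$a1)[j], ".", a)]] <- v
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(g$a1)
  out
}
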