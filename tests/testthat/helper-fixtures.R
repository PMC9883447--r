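# Small in-code fixtures shared across tests.

# dosage matrix with dimnames from a plain matrix
dos <- function(m, ids = NULL, loci = NULL) {
  m <- as.matrix(m)
  rownames(m) <- ids %||% sprintf("i%02d", seq_len(nrow(m)))
  colnames(m) <- loci %||% sprintf("L%02d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

toy_meta <- function(pops, countries = NULL, sex = NULL, ids = NULL) {
  n <- length(pops)
  sample_metadata(data.frame(
    individual = ids %||% sprintf("i%02d", seq_len(n)),
    population = pops,
    country = countries %||% pops,
    sex = sex %||% rep("unknown", n),
    X = as.numeric(factor(pops)), Y = rep(0, n)))
}

# two-population toy: pop A 3 individuals, pop B 3 individuals, 3 loci
toy_two_pops <- function() {
  d <- dos(rbind(c(0L, 1L, 2L),
                 c(1L, 1L, 2L),
                 c(0L, 0L, 1L),
                 c(2L, 1L, 0L),
                 c(2L, 2L, 1L),
                 c(1L, 2L, 0L)))
  list(g = snp_genotypes(d),
       meta = toy_meta(rep(c("A", "B"), each = 3)))
}

# independent haversine implementation (oracle for geographic distances)
haversine_oracle <- function(lon1, lat1, lon2, lat2, r_km = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r_km * asin(sqrt(a))
}

# brute-force allele-matching probabilities by exhaustive pair enumeration
# (oracle for the Beta estimator); alleles: vector of allele labels for all
# copies in one population
matching_within_oracle <- function(alleles) {
  n <- length(alleles)
  same <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) same <- same + (alleles[i] == alleles[j])
  }
  same / choose(n, 2)
}

matching_between_oracle <- function(a1, a2) {
  same <- 0L
  for (x in a1) for (y in a2) same <- same + (x == y)
  same / (length(a1) * length(a2))
}

# direct evaluation of the WC84 a/b/c components for one biallelic locus and
# two populations (oracle; follows the printed component formulas term by
# term, written independently of the package's vectorized path)
wc_pair_oracle <- function(dos1, dos2) {
  n1 <- sum(!is.na(dos1)); n2 <- sum(!is.na(dos2))
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  p1 <- sum(dos1, na.rm = TRUE) / (2 * n1)
  p2 <- sum(dos2, na.rm = TRUE) / (2 * n2)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  h1 <- mean(dos1 == 1, na.rm = TRUE)
  h2 <- mean(dos2 == 1, na.rm = TRUE)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}
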