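test_that("pairwise theta matches the component-by-component WC oracle", {
  set.seed(23)
  d <- matrix(sample(c(0:2, NA), 36, replace = TRUE,
                     prob = c(.35, .3, .3, .05)), 12, 3)
  # ensure every (pop, locus) cell has data
  d[1, ] <- 1L; d[7, ] <- 1L
  g <- snp_genotypes(dos(d))
  meta <- toy_meta(rep(c("A", "B"), each = 6))
  est <- pairwise_fst(g, meta)$matrix["A", "B"]
  comp <- sapply(1:3, function(l) wc_pair_oracle(d[1:6, l], d[7:12, l]))
  oracle <- sum(comp["a", ]) / sum(comp)
  expect_equal(unname(est), oracle, tolerance = 1e-12)
})

test_that("identical large populations give theta near zero", {
  set.seed(29)
  L <- 1000
  p <- runif(L, 0.1, 0.9)
  d <- matrix(rbinom(200 * L, 2, rep(p, each = 200)), 200, L)
  g <- snp_genotypes(dos(d))
  meta <- toy_meta(rep(c("A", "B"), each = 100))
  expect_lt(abs(pairwise_fst(g, meta)$matrix["A", "B"]), 0.01)
})

test_that("hierarchical decomposition: degenerate structures behave", {
  set.seed(31)
  L <- 300
  p <- runif(L, 0.2, 0.8)
  # all countries identical in frequency -> F_CT ~ 0
  d <- matrix(rbinom(60 * L, 2, rep(p, each = 60)), 60, L)
  g <- snp_genotypes(dos(d))
  meta <- toy_meta(rep(c("p1", "p2", "p3", "p4"), each = 15),
                   countries = rep(c("C1", "C2"), each = 30))
  h <- hierarchical_fstats(g, meta)
  expect_lt(abs(h$fstats["Fct"]), 0.01)

  # populations identical within countries, countries diverged:
  # F_SC ~ 0, F_CT > 0
  f <- 0.15
  d2 <- do.call(rbind, lapply(1:2, function(k) {
    pk <- rbeta(L, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    matrix(rbinom(30 * L, 2, rep(pk, each = 30)), 30, L)
  }))
  g2 <- snp_genotypes(dos(d2))
  h2 <- hierarchical_fstats(g2, meta)
  expect_lt(abs(h2$fstats["Fsc"]), 0.02)
  expect_gt(unname(h2$fstats["Fct"]), 0.05)

  # identity (1 - Fsc)(1 - Fct) = 1 - Fst on the component scale
  expect_equal((1 - h2$fstats[["Fsc"]]) * (1 - h2$fstats[["Fct"]]),
               1 - h2$fstats[["Fst"]], tolerance = 1e-9)

  expect_error(
    hierarchical_fstats(g, toy_meta(rep(c("p1", "p2"), each = 30),
                                    countries = rep("C1", 60))),
    "pairwise_fst")
})

test_that("with countries = populations the hierarchy reduces to WC theta", {
  set.seed(37)
  d <- matrix(rbinom(30 * 50, 2, 0.35), 30, 50)
  d[sample(length(d), 100)] <- NA
  g <- snp_genotypes(dos(d))
  meta <- toy_meta(rep(c("A", "B"), each = 15))  # country == population
  pw <- pairwise_fst(g, meta)$matrix["A", "B"]
  h <- hierarchical_fstats(g, meta)$fstats["Fst"]
  expect_equal(unname(h), unname(pw), tolerance = 1e-9)
})

test_that("chord distance: closed forms, metric behavior, BIONJ topology", {
  # p1 = (1,0), p2 = (0,1) at one locus -> D = (2/pi) * sqrt(2)
  g <- snp_genotypes(dos(rbind(matrix(0L, 3, 1), matrix(2L, 3, 1),
                               matrix(0L, 3, 1))))
  meta <- toy_meta(rep(c("A", "B", "C"), each = 3))
  cd <- chord_distance_tree(g, meta)
  expect_equal(unname(cd$distances$matrix["A", "B"]), (2 / pi) * sqrt(2),
               tolerance = 1e-12)
  expect_equal(unname(cd$distances$matrix["A", "B"]), 0.9003, tolerance = 1e-4)
  # identical frequency vectors -> 0
  expect_equal(unname(cd$distances$matrix["A", "C"]), 0)
  expect_true(isSymmetric(cd$distances$matrix))

  # empirical triangle inequality on random frequency triples
  set.seed(41)
  for (i in 1:20) {
    p <- runif(3)
    cosv <- function(pa, pb) sqrt(pa * pb) + sqrt((1 - pa) * (1 - pb))
    dd <- function(pa, pb) (2 / pi) * sqrt(2 * (1 - min(cosv(pa, pb), 1)))
    expect_lte(dd(p[1], p[3]), dd(p[1], p[2]) + dd(p[2], p[3]) + 1e-12)
  }

  # BIONJ recovers the generating topology ((A,B),(C,D))
  set.seed(43)
  L <- 400
  p0 <- runif(L, 0.3, 0.7)
  drift <- function(p, f) rbeta(L, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  anc1 <- drift(p0, 0.2); anc2 <- drift(p0, 0.2)
  freqs <- list(A = drift(anc1, 0.02), B = drift(anc1, 0.02),
                C = drift(anc2, 0.02), D = drift(anc2, 0.02))
  d4 <- do.call(rbind, lapply(freqs, function(pk)
    matrix(rbinom(12 * L, 2, rep(pk, each = 12)), 12, L)))
  g4 <- snp_genotypes(dos(d4))
  meta4 <- toy_meta(rep(c("A", "B", "C", "D"), each = 12))
  tr <- chord_distance_tree(g4, meta4)
  expect_s3_class(tr$tree, "phylo")
  expect_true(all(tr$tree$edge.length >= 0))
  cp <- ape::cophenetic.phylo(tr$tree)
  expect_lt(cp["A", "B"] + cp["C", "D"], cp["A", "C"] + cp["B", "D"])
})

test_that("great-circle distances match an independent haversine", {
  des <- population_design()
  meta <- sample_metadata(data.frame(
    individual = sprintf("i%02d", 1:19), population = des$population,
    country = des$country, X = des$X, Y = des$Y))
  geo <- geographic_distances(meta)
  expect_equal(unname(geo$matrix["1", "1"]), 0)
  oracle <- haversine_oracle(des$X[1], des$Y[1], des$X[19], des$Y[19])
  expect_equal(unname(geo$matrix["1", "19"]), oracle, tolerance = 0.1 / oracle)
  # antipodal points -> pi * R
  m2 <- sample_metadata(data.frame(individual = c("a", "b"),
                                   population = c("a", "b"),
                                   country = c("a", "b"),
                                   X = c(0, 180), Y = c(0, 0)))
  expect_equal(unname(geographic_distances(m2)$matrix["a", "b"]),
               pi * 6371, tolerance = 1e-6)
  bad <- m2; bad$Y <- c(0, 95)
  expect_error(geographic_distances(bad), "latitude")
})

test_that("Mantel test: self-correlation, invariances, vegan agreement", {
  set.seed(47)
  n <- 8
  m1 <- as.matrix(dist(matrix(runif(n * 2), n)))
  m2 <- as.matrix(dist(matrix(runif(n * 2), n)))
  dimnames(m1) <- dimnames(m2) <- list(letters[1:n], letters[1:n])
  d1 <- dist_matrix(m1); d2 <- dist_matrix(m2)

  self <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 100)

  # common relabeling leaves r unchanged
  idx <- sample(n)
  p1 <- dist_matrix(m1[idx, idx]); p2 <- dist_matrix(m2[idx, idx])
  expect_equal(mantel_test(p1, p2, n_perm = 9, seed = 1)$r,
               mantel_test(d1, d2, n_perm = 9, seed = 1)$r, tolerance = 1e-12)

  # monotone linear transform of either matrix leaves r unchanged
  d2b <- dist_matrix(2.5 * m2 + 3 * (m2 > 0))
  expect_equal(mantel_test(d1, d2b, n_perm = 9, seed = 1)$r,
               mantel_test(d1, d2, n_perm = 9, seed = 1)$r, tolerance = 1e-12)

  # r agrees with the vegan implementation
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(as.dist(m1), as.dist(m2), permutations = 99)
  expect_equal(mantel_test(d1, d2, n_perm = 99, seed = 2)$r,
               unname(vg$statistic), tolerance = 1e-12)

  expect_error(mantel_test(dist_matrix(m1[1:3, 1:3]),
                           dist_matrix(m2[1:3, 1:3])), "at least 4")
})

test_that("IBD linearization floors negative F_ST and rejects F_ST = 1", {
  set.seed(53)
  n <- 6
  f <- matrix(0.05, n, n); diag(f) <- 0
  f[1, 2] <- f[2, 1] <- -0.01
  dimnames(f) <- list(letters[1:n], letters[1:n])
  gm <- as.matrix(dist(cbind(runif(n, -5, 5), runif(n, 40, 45)))) * 100 + 1
  diag(gm) <- 0
  dimnames(gm) <- dimnames(f)
  res <- ibd_analysis(dist_matrix(f, "fst"), dist_matrix(gm, "geographic_km"),
                      seed = 3)
  expect_equal(res$n_floored, 1L)
  f2 <- f; f2[3, 4] <- f2[4, 3] <- 1
  expect_error(ibd_analysis(dist_matrix(f2, "fst"),
                            dist_matrix(gm, "geographic_km"), seed = 3),
               "linearized")
})

test_that("distance matrices round-trip through TSV", {
  m <- matrix(c(0, 1.5, 1.5, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  d <- dist_matrix(m, "fst")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dist_matrix(d, path)
  d2 <- read_dist_matrix(path, "fst")
  expect_equal(d2$matrix, d$matrix)
  expect_identical(d2$labels, d$labels)
})
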