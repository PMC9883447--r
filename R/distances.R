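# Distance matrices, chord-distance trees, geographic distances, Mantel
# permutation tests and isolation-by-distance regression.

#' Labelled symmetric distance matrix
#'
#' @param m symmetric numeric matrix with dimnames (zero diagonal enforced)
#' @param kind one of `"fst"`, `"chord"`, `"geographic_km"`,
#'   `"linearized_fst"`, `"log_km"`, `"other"`
#' @return `dist_matrix` object
#' @export
dist_matrix <- function(m, kind = "other") {
  assert_that(is.matrix(m) && nrow(m) == ncol(m), "matrix must be square")
  assert_that(!is.null(rownames(m)), "matrix needs labels")
  assert_that(!anyDuplicated(rownames(m)), "duplicate labels")
  assert_that(isTRUE(all.equal(m, t(m), tolerance = 1e-8,
                               check.attributes = FALSE)),
              "matrix must be symmetric")
  diag(m) <- 0
  structure(list(labels = rownames(m), matrix = m, kind = kind),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix[%s]: %d labels, mean off-diagonal %.4g\n",
              x$kind, length(x$labels),
              mean(x$matrix[upper.tri(x$matrix)], na.rm = TRUE)))
  invisible(x)
}

lower_vec <- function(d) d$matrix[lower.tri(d$matrix)]

#' Write/read a dist_matrix as a square TSV with header labels
#' @param d `dist_matrix`
#' @param path file path
#' @export
write_dist_matrix <- function(d, path) {
  utils::write.table(data.frame(label = d$labels, d$matrix,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @param kind kind tag for the re-read matrix
#' @export
read_dist_matrix <- function(path, kind = "other") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- colnames(m) <- as.character(df[[1]])
  dist_matrix(m, kind = kind)
}

#' Chord distances and BIONJ tree
#'
#' Per locus, `cos(theta) = sum_a sqrt(p1_a * p2_a)` and
#' `D = (2/pi) * sqrt(2 * (1 - cos(theta)))`; the population distance is the
#' mean over loci observed in both populations (`pooled` averages cos(theta)
#' over loci first, a published variant). With >= 3 populations the matrix is
#' translated into an unrooted tree by the variance-weighted neighbour-joining
#' algorithm (BIONJ); negative branch lengths are clamped to zero.
#'
#' @inheritParams allele_frequencies
#' @param averaging `"per_locus"` (default) or `"pooled"`
#' @return list: `distances` (`dist_matrix`, kind `"chord"`), `tree`
#'   (`ape::phylo` or NULL when < 3 populations)
#' @export
chord_distance_tree <- function(g, meta, averaging = c("per_locus", "pooled")) {
  averaging <- match.arg(averaging)
  af <- allele_frequencies(g, meta)
  pops <- af$populations
  np <- length(pops)
  m <- matrix(0, np, np, dimnames = list(pops, pops))
  for (i in seq_len(np - 1)) {
    for (j in seq(i + 1, np)) {
      cosv <- vapply(seq_along(af$freq), function(l) {
        f <- af$freq[[l]]
        if (af$n[i, l] == 0 || af$n[j, l] == 0) return(NA_real_)
        min(sum(sqrt(f[i, ] * f[j, ])), 1)
      }, numeric(1))
      if (averaging == "per_locus") {
        d <- mean((2 / pi) * sqrt(2 * (1 - cosv)), na.rm = TRUE)
      } else {
        d <- (2 / pi) * sqrt(2 * (1 - mean(cosv, na.rm = TRUE)))
      }
      m[i, j] <- m[j, i] <- d
    }
  }
  dm <- dist_matrix(m, kind = "chord")
  tree <- NULL
  if (np >= 3) {
    tree <- ape::bionj(stats::as.dist(m))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  list(distances = dm, tree = tree)
}

#' Great-circle distances between population coordinates
#'
#' Haversine distance with Earth radius 6371 km, from the per-population
#' longitude/latitude in the metadata.
#'
#' @param meta [sample_metadata()] (or any data frame with `population`, `X`,
#'   `Y`)
#' @return `dist_matrix` (kind `"geographic_km"`)
#' @export
geographic_distances <- function(meta) {
  pp <- unique(as.data.frame(meta)[, c("population", "X", "Y")])
  assert_that(all(abs(pp$Y) <= 90), "latitude outside [-90, 90]")
  np <- nrow(pp)
  m <- matrix(0, np, np, dimnames = list(pp$population, pp$population))
  for (i in seq_len(np - 1)) {
    for (j in seq(i + 1, np)) {
      m[i, j] <- m[j, i] <- geosphere::distHaversine(
        c(pp$X[i], pp$Y[i]), c(pp$X[j], pp$Y[j]), r = 6371000) / 1000
    }
  }
  dist_matrix(m, kind = "geographic_km")
}

#' Mantel permutation test
#'
#' Pearson correlation over lower-triangle entries; one matrix's labels are
#' permuted jointly over rows and columns;
#' `p = (#(r_perm >= r_obs) + 1)/(n_perm + 1)` for the `greater` tail
#' (`two.sided` doubles the smaller tail, `less` mirrors).
#'
#' @param d1,d2 `dist_matrix` objects over the same labels in the same order
#' @param n_perm permutations (default 999)
#' @param seed RNG seed
#' @param tail `"greater"` (default), `"less"` or `"two.sided"`
#' @return list with `r`, `p`, `n_perm`, `tail`
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = NULL,
                        tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  assert_that(identical(d1$labels, d2$labels),
              "distance matrices must share labels in the same order")
  n <- length(d1$labels)
  assert_that(n >= 4, "need at least 4 labels to permute meaningfully")
  v1 <- lower_vec(d1)
  r_obs <- stats::cor(v1, lower_vec(d2), use = "complete.obs")
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n)
      mp <- d2$matrix[idx, idx]
      stats::cor(v1, mp[lower.tri(mp)], use = "complete.obs")
    }, numeric(1))
  })
  p <- switch(tail,
    greater = (sum(r_perm >= r_obs) + 1) / (n_perm + 1),
    less = (sum(r_perm <= r_obs) + 1) / (n_perm + 1),
    two.sided = min(1, 2 * min((sum(r_perm >= r_obs) + 1) / (n_perm + 1),
                               (sum(r_perm <= r_obs) + 1) / (n_perm + 1))))
  list(r = r_obs, p = p, n_perm = n_perm, tail = tail)
}

#' Isolation-by-distance analysis
#'
#' By default applies Rousset's linearization: `F_ST/(1 - F_ST)` against
#' `log` geographic distance, then a one-tailed Mantel test plus the
#' least-squares slope over population pairs. Negative F_ST entries are
#' floored at 0 before the transform (count reported); `linearize = FALSE`
#' tests the raw matrices.
#'
#' @param fst `dist_matrix` of pairwise F_ST
#' @param geo `dist_matrix` of geographic distances (km)
#' @param linearize apply the Rousset transform (default TRUE)
#' @param n_perm,seed passed to [mantel_test()]
#' @return list with `r`, `p`, `slope`, `intercept`, `n_floored`,
#'   `linearize`
#' @export
ibd_analysis <- function(fst, geo, linearize = TRUE, n_perm = 999,
                         seed = NULL) {
  assert_that(identical(fst$labels, geo$labels),
              "F_ST and geographic matrices must share labels")
  f <- fst$matrix
  gm <- geo$matrix
  n_floored <- 0L
  if (linearize) {
    assert_that(all(f[upper.tri(f)] < 1, na.rm = TRUE),
                "F_ST = 1 entry cannot be linearized")
    neg <- f < 0
    n_floored <- sum(neg[upper.tri(neg)])
    f[neg] <- 0
    f <- f / (1 - f)
    off <- upper.tri(gm) | lower.tri(gm)
    assert_that(all(gm[off] > 0, na.rm = TRUE),
                "zero geographic distance cannot be log-transformed")
    gm[off] <- log(gm[off])
    diag(gm) <- 0
  }
  d_f <- dist_matrix(f, kind = if (linearize) "linearized_fst" else "fst")
  d_g <- dist_matrix(gm, kind = if (linearize) "log_km" else "geographic_km")
  mt <- mantel_test(d_f, d_g, n_perm = n_perm, seed = seed, tail = "greater")
  fit <- stats::lm(lower_vec(d_f) ~ lower_vec(d_g))
  list(r = mt$r, p = mt$p,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_floored = n_floored, linearize = linearize)
}
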