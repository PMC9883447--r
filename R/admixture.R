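# Admixture inference by regularized nonnegative matrix factorization of the
# one-hot genotype-class matrix X (individuals x 3*loci, classes {0,1,2}):
# X ~ Q G with Q row-stochastic (ancestry fractions) and G carrying, per
# cluster and locus, a probability vector over the three genotype classes.
# Fitting alternates ridge-penalized least squares for Q (penalty weight
# `alpha / n_loci`, scaled per locus so the regularization's pull on the
# ancestry rows does not grow with panel size) and least squares for G, each
# followed by projection onto its simplex constraints; a monotone safeguard keeps a block update only if the
# masked penalized objective does not increase, so the objective is
# non-increasing by construction. Missing and held-out cells are imputed by
# the current reconstruction (EM-style) and excluded from the objective.
# Model choice uses masked cross-entropy: a random fraction of non-missing
# genotype cells is blinded during fitting and their predicted class
# probabilities scored afterwards.

one_hot_classes <- function(dosage) {
  n <- nrow(dosage); L <- ncol(dosage)
  X <- matrix(0, n, 3L * L)
  for (cls in 0:2) {
    idx <- which(dosage == cls)
    X[(((idx - 1L) %/% n) * 3L + cls) * n + ((idx - 1L) %% n) + 1L] <- 1
  }
  X
}

# normalize rows to the probability simplex (negative entries clipped)
project_rows_simplex <- function(m) {
  m[m < 0] <- 0
  s <- rowSums(m)
  bad <- s <= 0
  if (any(bad)) m[bad, ] <- 1
  m / rowSums(m)
}

# project G so each (cluster, locus) class triple is a probability vector
project_g_simplex <- function(G) {
  K <- nrow(G); L3 <- ncol(G)
  G[G < 0] <- 0
  idx <- rep(seq_len(L3 %/% 3L), each = 3L)
  s <- t(rowsum(t(G), idx))               # K x L sums over triples
  s_full <- s[, idx, drop = FALSE]
  bad <- s_full <= 0
  G[bad] <- 1 / 3
  s_full[bad] <- 1
  G / s_full
}

nmf_admixture_single <- function(X, W_obs, K, alpha, seed, max_iter, tol) {
  n <- nrow(X); L3 <- ncol(X)
  alpha <- alpha / (L3 / 3)  # per-locus scaling of the ridge weight
  # the mask is mostly 1: track the zero cells by index and keep X pre-masked
  idx0 <- which(W_obs == 0)
  Xobs <- X
  Xobs[idx0] <- 0
  # masked SSE via full-matrix pass minus the masked cells' contribution
  msse <- function(P, Q) {
    d <- Xobs - P
    sum(d * d) - sum(d[idx0]^2) + alpha * sum(Q * Q)
  }
  fill <- function(P) {
    Xf <- Xobs
    Xf[idx0] <- P[idx0]
    Xf
  }
  gl_freq <- colSums(Xobs) / pmax(colSums(W_obs), 1)
  init <- with_seed(seed, {
    Q <- matrix(stats::runif(n * K, 0.1, 1), n, K)
    G <- matrix(rep(gl_freq, each = K), K, L3) *
      matrix(stats::runif(K * L3, 0.5, 1.5), K, L3)
    list(Q = Q, G = G)
  })
  Q <- project_rows_simplex(init$Q)
  G <- project_g_simplex(init$G)
  P <- Q %*% G
  obj <- msse(P, Q)
  obj_trace <- obj
  converged <- FALSE
  iter <- 0L
  step_q <- step_g <- 1
  for (iter in seq_len(max_iter)) {
    # Q block: try the ridge-ALS candidate; fall back to projected gradient
    # with backtracking on the masked objective (monotone either way)
    Xfill <- fill(P)
    Qc <- tryCatch(
      project_rows_simplex(Xfill %*% t(G) %*%
                             solve(G %*% t(G) + diag(alpha, K))),
      error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(Qc)) {
      Pc <- Qc %*% G
      objc <- msse(Pc, Qc)
      if (objc < obj) { Q <- Qc; P <- Pc; obj <- objc; accepted <- TRUE }
    }
    if (!accepted) {
      R <- P - Xobs
      R[idx0] <- 0
      grad <- 2 * (R %*% t(G)) + 2 * alpha * Q
      t_s <- step_q * 2
      repeat {
        Qc <- project_rows_simplex(Q - t_s * grad)
        Pc <- Qc %*% G
        objc <- msse(Pc, Qc)
        if (objc < obj) { Q <- Qc; P <- Pc; obj <- objc; step_q <- t_s; break }
        t_s <- t_s / 2
        if (t_s < 1e-14) break
      }
    }
    # G block: same strategy with the class-triple simplex
    Xfill <- fill(P)
    Gc <- tryCatch(
      project_g_simplex(solve(crossprod(Q) + diag(1e-8, K),
                              crossprod(Q, Xfill))),
      error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(Gc)) {
      Pc <- Q %*% Gc
      objc <- msse(Pc, Q)
      if (objc < obj) { G <- Gc; P <- Pc; obj <- objc; accepted <- TRUE }
    }
    if (!accepted) {
      R <- P - Xobs
      R[idx0] <- 0
      grad <- 2 * crossprod(Q, R)
      t_s <- step_g * 2
      repeat {
        Gc <- project_g_simplex(G - t_s * grad)
        Pc <- Q %*% Gc
        objc <- msse(Pc, Q)
        if (objc < obj) { G <- Gc; P <- Pc; obj <- objc; step_g <- t_s; break }
        t_s <- t_s / 2
        if (t_s < 1e-14) break
      }
    }
    obj_trace <- c(obj_trace, obj)
    prev <- obj_trace[length(obj_trace) - 1]
    if (prev - obj <= tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  list(Q = Q, G = G, P = P, objective = obj, objective_trace = obj_trace,
       iterations = iter, converged = converged)
}

#' Fit admixture models by regularized NMF with masked cross-entropy
#'
#' @param g [snp_genotypes()] (biallelic dosage matrix)
#' @param K number of ancestral clusters (>= 1)
#' @param n_reps independent repetitions, each with its own initialization
#'   and held-out mask (default 20)
#' @param mask_fraction fraction of non-missing genotype cells blinded per
#'   repetition for the cross-entropy estimate (default 0.10)
#' @param alpha ridge regularization weight on the ancestry matrix Q
#'   (default 100)
#' @param seed base seed; repetition r uses a seed derived from (seed, r),
#'   so the same data/seed/mask reproduce a fit bit-for-bit
#' @param max_iter,tol convergence controls (relative objective change;
#'   defaults 500 and 1e-6)
#' @return list of `admixture_fit` objects (one per repetition), each with
#'   `K`, `Q` (individuals x K, row-stochastic), `G` (K x 3*loci class
#'   frequencies), `cross_entropy`, `mask_fraction`, `alpha`, `seed`,
#'   `iterations`, `converged`
#' @export
admixture_fit <- function(g, K, n_reps = 20, mask_fraction = 0.10,
                          alpha = 100, seed = NULL, max_iter = 500,
                          tol = 1e-6) {
  assert_that(is_snp(g), "admixture_fit expects snp_genotypes")
  assert_that(K >= 1, "K must be >= 1")
  assert_that(K <= nrow(g$dosage), "K exceeds the number of individuals")
  dosage <- g$dosage
  n <- nrow(dosage); L <- ncol(dosage)
  X <- one_hot_classes(dosage)
  obs_cell <- !is.na(dosage)
  nm <- which(obs_cell)
  fits <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- child_seed(seed %||% 0L, r)
    held <- with_seed(rep_seed, {
      sample(nm, size = max(1L, round(mask_fraction * length(nm))))
    })
    W_cell <- obs_cell
    W_cell[held] <- FALSE
    # expand the per-genotype mask to the three class columns of each locus
    W <- W_cell[, rep(seq_len(L), each = 3L)] + 0
    fit <- nmf_admixture_single(X, W, K, alpha, rep_seed, max_iter, tol)
    ce <- masked_cross_entropy(fit$P, dosage, held)
    fits[[r]] <- structure(
      list(K = K, Q = structure(fit$Q, dimnames = list(rownames(dosage), NULL)),
           G = fit$G, cross_entropy = ce, mask_fraction = mask_fraction,
           alpha = alpha, seed = rep_seed, iterations = fit$iterations,
           converged = fit$converged, objective = fit$objective,
           objective_trace = fit$objective_trace,
           loci = colnames(dosage)),
      class = "admixture_fit")
  }
  fits
}

# X columns are ordered class-fastest: (locus1: c0,c1,c2), (locus2: ...)
masked_cross_entropy <- function(P, dosage, held_cells) {
  n <- nrow(dosage)
  loci <- ((held_cells - 1L) %/% n) + 1L
  inds <- ((held_cells - 1L) %% n) + 1L
  cls <- dosage[held_cells]
  p0 <- pmax(P[cbind(inds, 3L * (loci - 1L) + 1L)], 1e-10)
  p1 <- pmax(P[cbind(inds, 3L * (loci - 1L) + 2L)], 1e-10)
  p2 <- pmax(P[cbind(inds, 3L * (loci - 1L) + 3L)], 1e-10)
  tot <- p0 + p1 + p2
  probs <- ifelse(cls == 0L, p0, ifelse(cls == 1L, p1, p2)) / tot
  -mean(log(probs))
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf(
    "admixture_fit K=%d: cross-entropy %.4f, %d iterations%s (alpha=%g)\n",
    x$K, x$cross_entropy, x$iterations,
    if (x$converged) "" else " (not converged)", x$alpha))
  invisible(x)
}

#' Run admixture over a range of K
#'
#' @inheritParams admixture_fit
#' @param k_range integer vector of K values (default 1:7)
#' @return list: `fits` (list over K of repetition lists), `entropy` (data
#'   frame K, rep, cross_entropy), `best` (per K, the lowest-entropy fit)
#' @export
admixture_scan <- function(g, k_range = 1:7, n_reps = 20,
                           mask_fraction = 0.10, alpha = 100, seed = NULL,
                           max_iter = 500, tol = 1e-6) {
  fits <- lapply(k_range, function(K) {
    admixture_fit(g, K, n_reps = n_reps, mask_fraction = mask_fraction,
                  alpha = alpha, seed = child_seed(seed %||% 0L, 1000L + K),
                  max_iter = max_iter, tol = tol)
  })
  names(fits) <- as.character(k_range)
  entropy <- do.call(rbind, lapply(seq_along(k_range), function(i) {
    data.frame(K = k_range[i], rep = seq_along(fits[[i]]),
               cross_entropy = vapply(fits[[i]], `[[`, numeric(1),
                                      "cross_entropy"))
  }))
  best <- lapply(fits, function(fl) fl[[which.min(
    vapply(fl, `[[`, numeric(1), "cross_entropy"))]])
  list(fits = fits, entropy = entropy, best = best, k_range = k_range)
}

#' Choose K from masked cross-entropies (plateau rule)
#'
#' K* is the smallest K whose median masked cross-entropy lies within one
#' median absolute deviation (of the entropies at the minimizing K) of the
#' global minimum median. Reading a cross-entropy boxplot by eye picks the K
#' where the curve flattens; this rule makes that explicit.
#'
#' @param entropy data frame with columns `K` and `cross_entropy` (as from
#'   [admixture_scan()]`$entropy`)
#' @return list: `k_star`, `table` (per-K median and MAD), `threshold`
#' @export
select_k <- function(entropy) {
  ks <- sort(unique(entropy$K))
  if (length(ks) == 1) {
    warnf("single K supplied; returning it as-is")
    return(list(k_star = ks, table = data.frame(
      K = ks, median = stats::median(entropy$cross_entropy), mad = 0),
      threshold = stats::median(entropy$cross_entropy)))
  }
  reps_per_k <- table(entropy$K)
  assert_that(all(reps_per_k >= 2),
              "need >= 2 repetitions per K for the plateau rule")
  med <- vapply(ks, function(k) {
    stats::median(entropy$cross_entropy[entropy$K == k])
  }, numeric(1))
  k_min <- ks[which.min(med)]
  mad_min <- stats::mad(entropy$cross_entropy[entropy$K == k_min],
                        constant = 1)
  threshold <- min(med) + mad_min
  k_star <- ks[which(med <= threshold)[1]]
  list(k_star = k_star,
       table = data.frame(K = ks, median = med,
                          mad = vapply(ks, function(k) {
                            stats::mad(entropy$cross_entropy[entropy$K == k],
                                       constant = 1)
                          }, numeric(1))),
       threshold = threshold)
}

#' Align cluster labels of one ancestry matrix to a reference
#'
#' Exhaustive search over cluster permutations (K <= 7 throughout) for the
#' relabeling maximizing the summed correlation between matched Q columns.
#'
#' @param q_ref,q reference and target ancestry matrices (same individuals,
#'   same K)
#' @return `q` with columns permuted to match `q_ref`
#' @export
match_clusters <- function(q_ref, q) {
  assert_that(all(dim(q_ref) == dim(q)), "Q matrices must match in shape")
  K <- ncol(q)
  if (K == 1) return(q)
  cm <- suppressWarnings(stats::cor(q_ref, q))
  cm[is.na(cm)] <- 0
  perms <- all_permutations(K)
  scores <- apply(perms, 1, function(pr) sum(cm[cbind(seq_len(K), pr)]))
  q[, perms[which.max(scores), ], drop = FALSE]
}

# fraction of individuals assigned to the same (relabeled) cluster
assignment_concordance <- function(q_ref, q) {
  qm <- match_clusters(q_ref, q)
  mean(max.col(qm, ties.method = "first") ==
         max.col(q_ref, ties.method = "first"))
}

#' SNP-subsampling resolution experiment
#'
#' Refits the admixture model on random locus subsets of decreasing size and
#' measures the concordance of individual hard assignments with the
#' full-data fit (after optimal cluster relabeling).
#'
#' @inheritParams admixture_fit
#' @param sizes subset sizes (default c(3000, 2000, 1000, 500, 200, 100);
#'   sizes above the locus count are an error)
#' @param K number of clusters for the comparison fits
#' @param n_reps repetitions per fit (best-of-reps used; default 5)
#' @return list: `full` (full-data best fit), `per_size` (data frame size,
#'   concordance, cross_entropy), `fits` (per-size best fits)
#' @export
snp_subsample_experiment <- function(g, sizes = c(3000, 2000, 1000, 500, 200,
                                                  100),
                                     K, n_reps = 5, mask_fraction = 0.10,
                                     alpha = 100, seed = NULL,
                                     max_iter = 500, tol = 1e-6) {
  L <- ncol(g$dosage)
  assert_that(all(sizes <= L), "subset size exceeds the %d available loci", L)
  best_of <- function(gg, s) {
    fl <- admixture_fit(gg, K, n_reps = n_reps, mask_fraction = mask_fraction,
                        alpha = alpha, seed = s, max_iter = max_iter,
                        tol = tol)
    fl[[which.min(vapply(fl, `[[`, numeric(1), "cross_entropy"))]]
  }
  full <- best_of(g, child_seed(seed %||% 0L, 1L))
  fits <- vector("list", length(sizes))
  conc <- ce <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    idx <- if (sizes[i] == L) seq_len(L) else {
      with_seed(child_seed(seed %||% 0L, 100L + i),
                sample.int(L, sizes[i]))
    }
    fit <- best_of(subset_snps(g, loci = idx),
                   child_seed(seed %||% 0L, 200L + i))
    fits[[i]] <- fit
    conc[i] <- assignment_concordance(full$Q, fit$Q)
    ce[i] <- fit$cross_entropy
  }
  list(full = full,
       per_size = data.frame(size = sizes, concordance = conc,
                             cross_entropy = ce),
       fits = fits)
}
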