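#' Principal component analysis of individual genotypes
#'
#' Microsatellites are expanded to per-allele indicator dosages; SNPs use the
#' alternate-allele dosage. Columns are mean-centered, missing entries
#' imputed by the column mean (i.e. zero after centering), and the
#' eigendecomposition of the covariance taken. Columns are unscaled by
#' default, matching the convention that common alleles carry more weight.
#'
#' @inheritParams allele_frequencies
#' @param g [snp_genotypes()] or [microsat_genotypes()]
#' @param n_axes number of axes to return (default 10, capped by rank)
#' @param scale scale columns to unit variance (default FALSE)
#' @return `pca_result`: list with `scores` (individuals x axes),
#'   `var_fraction`, `imputation = "column_mean"`
#' @export
genotype_pca <- function(g, n_axes = 10, scale = FALSE) {
  x <- allele_dosage_matrix(g)
  assert_that(nrow(x) >= 2 && ncol(x) >= 2, "need >= 2 individuals and loci")
  all_na <- colSums(!is.na(x)) == 0
  if (any(all_na)) {
    warnf("dropping %d all-missing column(s)", sum(all_na))
    x <- x[, !all_na, drop = FALSE]
  }
  mu <- colMeans(x, na.rm = TRUE)
  xc <- sweep(x, 2, mu)
  xc[is.na(xc)] <- 0
  if (scale) {
    sd <- apply(xc, 2, stats::sd)
    sd[sd == 0] <- 1
    xc <- sweep(xc, 2, sd, "/")
  }
  sv <- svd(xc, nu = min(n_axes, dim(xc)), nv = 0)
  keep <- seq_len(min(n_axes, length(sv$d)))
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], nrow = length(keep))
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", keep)
  tot_var <- sum(xc^2)
  structure(list(scores = scores,
                 var_fraction = sv$d[keep]^2 / tot_var,
                 imputation = "column_mean"),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d individuals, %d axes (PC1 %.1f%%, PC2 %.1f%%)\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$var_fraction[1],
              if (length(x$var_fraction) > 1) 100 * x$var_fraction[2] else NA))
  invisible(x)
}
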