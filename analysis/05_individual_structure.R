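#!/usr/bin/env Rscript
# Individual-level structure: genotype PCA per marker set, admixture scans
# with masked cross-entropy K selection (K = 1-6, 3 maskings per K — scaled
# from the study's 20), the SNP-subsampling resolution experiment, the
# >= 70%-completeness sensitivity rerun, and the sex-bias test.

library(popresolve)

seed <- 42
snp <- read_snp_table("results/data/snp_filtered.tsv", "tsv")
ms <- read_microsat_table("results/data/microsat.tsv")
meta <- read_metadata("results/data/metadata.csv")

for (marker in c("snp", "microsat")) {
  g <- if (marker == "snp") snp else ms
  pc <- genotype_pca(g, n_axes = 4)
  write.table(data.frame(individual = rownames(pc$scores),
                         population = meta$population, pc$scores),
              sprintf("results/pca_%s.tsv", marker), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("PCA (%s): PC1 %.1f%%, PC2 %.1f%%", marker,
                  100 * pc$var_fraction[1], 100 * pc$var_fraction[2]))
}

sc <- admixture_scan(snp, k_range = 1:6, n_reps = 3, seed = seed)
write.table(sc$entropy, "results/admixture_entropy_snp.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
ks <- select_k(sc$entropy)
message(sprintf("SNP admixture: K* = %d (plateau rule)", ks$k_star))
best <- sc$best[[as.character(ks$k_star)]]
write.table(data.frame(individual = rownames(best$Q),
                       population = meta$population, round(best$Q, 4)),
            "results/ancestry_snp.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# >= 70% completeness sensitivity rerun
complete <- rowMeans(!is.na(snp$dosage)) >= 0.7
sub <- subset_snps(snp, individuals = which(complete))
sc70 <- admixture_scan(sub, k_range = 1:6, n_reps = 3, seed = seed + 1)
ks70 <- select_k(sc70$entropy)
message(sprintf("completeness >= 70%% subset (n = %d): K* = %d",
                sum(complete), ks70$k_star))

ex <- snp_subsample_experiment(snp, sizes = c(3000, 2000, 1000, 500, 200, 100),
                               K = ks$k_star, n_reps = 3, seed = seed + 2)
write.table(ex$per_size, "results/subsample_concordance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("subsampling concordance with the full-data ancestry:")
print(ex$per_size, row.names = FALSE)

for (marker in c("snp", "microsat")) {
  sb <- sexbias_test(if (marker == "snp") snp else ms, meta,
                     seed = seed + 3)
  message(sprintf(
    "sex bias (%s): mAIc M %.3f / F %.3f, t = %.2f, p = %.2f (perm p = %.2f)",
    marker, sb$maic["M"], sb$maic["F"], sb$t, sb$p_t, sb$p_perm))
}
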