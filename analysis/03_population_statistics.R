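#!/usr/bin/env Rscript
# Per-population diversity for both marker sets (H_O, H_S, F_IS, rarefied
# allelic richness, population-specific F_ST), overall statistics with
# 1000-draw bootstrap CIs, and the gene-diversity-versus-frequency envelope
# used to screen outlier loci.

library(popresolve)

seed <- 42
snp <- read_snp_table("results/data/snp_filtered.tsv", "tsv")
ms <- read_microsat_table("results/data/microsat.tsv")
meta <- read_metadata("results/data/metadata.csv")

for (marker in c("snp", "microsat")) {
  g <- if (marker == "snp") snp else ms
  tab <- population_table(g, meta)
  write.table(format(tab, digits = 3), sprintf("results/table1_%s.tsv", marker),
              sep = "\t", quote = FALSE, row.names = FALSE)
  bs <- basic_stats(g, meta, n_boot = 1000, seed = seed)
  write.table(bs$ci, sprintf("results/overall_%s.tsv", marker), sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("%s: mean Ho %.3f, Hs %.3f, Ht %.3f, overall Fis %.3f",
                  marker, bs$overall["Ho"], bs$overall["Hs"],
                  bs$overall["Ht"], bs$overall["Fis"]))
}

# envelope: per-SNP pooled frequency vs H_S with the printed 95% band
bs_snp <- basic_stats(snp, meta)
af <- allele_frequencies(snp, meta)
p_pool <- vapply(seq_along(af$freq), function(l) {
  w <- af$n[, l]
  sum(af$freq[[l]][, "alt"] * w, na.rm = TRUE) / sum(w)
}, numeric(1))
hs_locus <- colMeans(bs_snp$per_locus$hs, na.rm = TRUE)
f_it <- 1 - bs_snp$overall[["Ho"]] / bs_snp$overall[["Ht"]]
env <- hs_envelope_bounds(p_pool, f_it, nrow(snp$dosage))
env_tab <- data.frame(locus = colnames(snp$dosage), p = p_pool,
                      hs = hs_locus, env)
env_tab$outlier <- env_tab$hs < env_tab$lower | env_tab$hs > env_tab$upper
write.table(format(env_tab, digits = 4), "results/hs_envelope_snp.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("envelope (f_IT = %.3f): %d of %d SNPs outside the 95%% band",
                f_it, sum(env_tab$outlier, na.rm = TRUE), nrow(env_tab)))
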