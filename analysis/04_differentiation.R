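#!/usr/bin/env Rscript
# Differentiation geography: pairwise Weir-Cockerham F_ST for both marker
# sets, the marker-to-marker Mantel comparison, isolation by distance
# (Rousset linearization), chord-distance BIONJ trees, and hierarchical
# F-statistics partitioning variance between countries and populations.

library(popresolve)

seed <- 42
snp <- read_snp_table("results/data/snp_filtered.tsv", "tsv")
ms <- read_microsat_table("results/data/microsat.tsv")
meta <- read_metadata("results/data/metadata.csv")

fst <- list(snp = pairwise_fst(snp, meta), microsat = pairwise_fst(ms, meta))
geo <- geographic_distances(meta)
write_dist_matrix(fst$snp, "results/fst_snp.tsv")
write_dist_matrix(fst$microsat, "results/fst_microsat.tsv")
write_dist_matrix(geo, "results/geographic_km.tsv")

message(sprintf("mean pairwise F_ST: SNP %.3f, microsatellite %.3f",
                mean_pairwise_fst(fst$snp), mean_pairwise_fst(fst$microsat)))

mk <- mantel_test(fst$snp, fst$microsat, seed = seed, tail = "two.sided")
message(sprintf("marker-set Mantel: r = %.2f, p = %.3g", mk$r, mk$p))

for (marker in names(fst)) {
  ibd <- ibd_analysis(fst[[marker]], geo, seed = seed + 1)
  message(sprintf("IBD (%s): Mantel r = %.2f, p = %.3g, slope = %.4g",
                  marker, ibd$r, ibd$p, ibd$slope))
  ct <- chord_distance_tree(if (marker == "snp") snp else ms, meta)
  write_dist_matrix(ct$distances, sprintf("results/chord_%s.tsv", marker))
  ape::write.tree(ct$tree, sprintf("results/chord_%s.nwk", marker))
  h <- hierarchical_fstats(if (marker == "snp") snp else ms, meta,
                           n_boot = 1000, seed = seed + 2)
  write.table(h$ci, sprintf("results/hierarchical_%s.tsv", marker),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("hierarchical (%s): Fsc = %.3f, Fct = %.3f", marker,
                  h$fstats["Fsc"], h$fstats["Fct"]))
}
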