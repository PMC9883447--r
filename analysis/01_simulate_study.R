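#!/usr/bin/env Rscript
# Generate the synthetic study: 19 colonies in 7 countries with the field
# design's sample sizes and coordinates, 4994 SNPs (with read depths) and 11
# microsatellites, hierarchical differentiation F_CT = 0.058 / F_SC = 0.019,
# missingness and low coverage concentrated in colony 9. Two colonies act as
# migratory hubs hosting unadmixed migrants from a neighbouring deme.

library(popresolve)

seed <- 42
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- paper_like_config()
ds <- simulate_dataset(cfg, seed = seed)
# hub colonies: syntopic, non-admixed foreign ancestries (no sex skew)
ds <- inject_migrants(ds, hub_population = "2", source_population = "4",
                      fraction = 0.3, seed = seed + 1)
ds <- inject_migrants(ds, hub_population = "15", source_population = "17",
                      fraction = 0.3, seed = seed + 2)
gd <- simulate_read_depths(ds$snp, cfg, meta = ds$meta, seed = seed + 3)

write_snp_table(gd, file.path(out, "snp_raw.tsv"))
write_microsat_table(ds$microsat, file.path(out, "microsat.tsv"))
write_metadata(ds$meta, file.path(out, "metadata.csv"))
jsonlite::write_json(
  list(seed = seed, migrants = ds$truth$migrants,
       f_ct = cfg$f_ct, f_sc = cfg$f_sc,
       n_snps = cfg$n_snps, n_microsats = cfg$n_microsats),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

message(sprintf("simulated %d individuals x %d SNPs + %d microsatellites",
                nrow(gd$dosage), ncol(gd$dosage), ncol(ds$microsat$a1)))
message(sprintf("injected %d hub migrants; outputs in %s",
                length(ds$truth$migrants), out))
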