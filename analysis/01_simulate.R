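#!/usr/bin/env Rscript
# Simulate a diploid DNase Hi-C experiment on a synthetic X chromosome:
# a bipartite maternal homolog (the inactive X in a Patski-like skewing,
# hinge planted at bin 40 of 100) and a globular paternal homolog, then
# emit SNP-annotated pair records. Writes results/run/.

suppressPackageStartupMessages(library(diphic))
seed <- 1L
out <- "results/run"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

xi <- make_structure(100, "bipartite", hinge_index = 40, seed = seed)
xa <- make_structure(100, "globular", seed = seed + 1L)
map_m <- simulate_contact_map(xi, alpha = -3, depth = 2e5, seed = seed + 2L)
map_p <- simulate_contact_map(xa, alpha = -3, depth = 2e5, seed = seed + 3L)
map_m$haplotype <- "maternal"; map_p$haplotype <- "paternal"
pairs <- simulate_pairs(list(maternal = map_m, paternal = map_p),
                        snp_informative_rate = 0.3, dup_rate = 0.05,
                        seed = seed + 4L)

write_structure(xi, file.path(out, "true_structure_xi.tsv"))
write_structure(xa, file.path(out, "true_structure_xa.tsv"))
write_sparse_map(map_m, file.path(out, "true_map_maternal"))
write_sparse_map(map_p, file.path(out, "true_map_paternal"))
write_pairs(pairs, file.path(out, "pairs.tsv"))

message(sprintf(
  "simulated %d pair records (%.0f per homolog expected); %.1f%% carry >= 1 informative SNP end",
  nrow(pairs), 2e5, 100 * mean(pairs$allele1 != "." | pairs$allele2 != ".")))
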