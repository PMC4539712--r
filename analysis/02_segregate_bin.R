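#!/usr/bin/env Rscript
# Haplotype segregation (MAPQ >= 30 filter, PCR-duplicate removal,
# SNP-evidence classification) and contact-map binning at 1 Mb.

suppressPackageStartupMessages(library(diphic))
out <- "results/run"

pairs <- read_pairs(file.path(out, "pairs.tsv"))
seg <- segregate_pairs(pairs, mapq_min = 30)
bt <- read_sparse_map(file.path(out, "true_map_maternal"))$bins
maps <- bin_pairs(seg$pairs, bt)

write_sparse_map(maps$maternal, file.path(out, "map_certain_maternal"))
write_sparse_map(maps$paternal, file.path(out, "map_certain_paternal"))
write_sparse_map(maps$uncertain, file.path(out, "map_uncertain_pooled"))

counts <- as.data.frame(seg$summary$categories)
names(counts) <- c("category", "pairs")
counts <- rbind(counts,
                data.frame(category = c("removed_mapq",
                                        "removed_duplicates"),
                           pairs = c(seg$summary$removed_mapq,
                                     seg$summary$removed_duplicates)))
write.table(counts, file.path(out, "category_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf(
  "kept %d unique high-quality molecules: %d maternal, %d paternal, %d allele-uncertain (%d MAPQ-removed, %d duplicates)",
  sum(seg$summary$categories), seg$summary$categories[["maternal"]],
  seg$summary$categories[["paternal"]],
  seg$summary$categories[["uncertain"]], seg$summary$removed_mapq,
  seg$summary$removed_duplicates))
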