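#!/usr/bin/env Rscript
# Empirical-Bayes EM assignment of allele-uncertain contacts to the two
# haplotype maps, with the recovery gain measured against the simulated
# ground truth.

suppressPackageStartupMessages(library(diphic))
out <- "results/run"

cm <- read_sparse_map(file.path(out, "map_certain_maternal"))
cp <- read_sparse_map(file.path(out, "map_certain_paternal"))
u <- read_sparse_map(file.path(out, "map_uncertain_pooled"))
em <- em_assign_uncertain(list(maternal = cm, paternal = cp), u,
                          tol = 1e-3, max_iter = 100)
write_sparse_map(em$maternal, file.path(out, "map_inferred_maternal"))
write_sparse_map(em$paternal, file.path(out, "map_inferred_paternal"))
write.table(data.frame(iteration = seq_along(em$state$delta_trace),
                       max_weight_change = em$state$delta_trace),
            file.path(out, "em_trace.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read_sparse_map(file.path(out, "true_map_maternal"))
ut <- upper.tri(truth$counts, diag = TRUE)
cor_cert <- cor(cm$counts[ut], truth$counts[ut])
cor_inf <- cor(em$maternal$counts[ut], truth$counts[ut])
message(sprintf(
  "EM %s in %d iterations; maternal-map correlation with truth: %.4f (certain reads only) -> %.4f (inferred)",
  if (em$state$converged) "converged" else "stopped", em$state$iterations,
  cor_cert, cor_inf))
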