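#!/usr/bin/env Rscript
# Preprocess the allelic maps (zero self-ligation tridiagonal, mask the
# lowest-2% coverage bins) and balance them by iterative correction.

suppressPackageStartupMessages(library(diphic))
out <- "results/run"

for (hap in c("maternal", "paternal")) {
  cm <- read_sparse_map(file.path(out, paste0("map_certain_", hap)))
  pp <- preprocess_map(cm, coverage_quantile = 0.02)
  bal <- ice_normalize(pp, tol = 1e-4)
  write_sparse_map(pp, file.path(out, paste0("map_preprocessed_", hap)))
  write_sparse_map(bal, file.path(out, paste0("map_balanced_", hap)))
  s <- rowSums(bal$counts)[bal$mask]
  message(sprintf(
    "%s: masked %d of %d bins; balancing converged = %s in %d iterations (row-sum CV %.2e)",
    hap, sum(!pp$mask), nrow(cm$counts), attr(bal, "converged"),
    max(attr(bal, "iterations")), sd(s) / mean(s)))
}
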