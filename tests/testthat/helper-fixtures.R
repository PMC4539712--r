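# Shared fixtures, built in code at test time.

# minimal pair-record data.frame
make_pair_df <- function(chrom1, pos1, chrom2, pos2,
                         allele1 = ".", allele2 = ".",
                         mapq1 = 60L, mapq2 = 60L) {
  n <- max(length(pos1), length(pos2))
  data.frame(read_id = sprintf("r%03d", seq_len(n)),
             chrom1 = rep_len(chrom1, n), pos1 = rep_len(pos1, n),
             strand1 = "+", chrom2 = rep_len(chrom2, n),
             pos2 = rep_len(pos2, n), strand2 = "-",
             mapq1 = rep_len(mapq1, n), mapq2 = rep_len(mapq2, n),
             allele1 = rep_len(allele1, n), allele2 = rep_len(allele2, n),
             stringsAsFactors = FALSE)
}

# symmetric Poisson map with a given rate matrix (upper triangle drawn)
rpois_map <- function(lam, seed) {
  set.seed(seed)
  n <- nrow(lam)
  m <- matrix(0, n, n)
  ut <- upper.tri(lam, diag = TRUE)
  m[ut] <- stats::rpois(sum(ut), lam[ut])
  m + t(m) - diag(diag(m))
}

# constant-block matrix realizing given block mean frequencies at boundary h
block_map <- function(n, h, f1, f2, f_inter) {
  m <- matrix(f_inter, n, n)
  m[seq_len(h), seq_len(h)] <- f1
  m[(h + 1):n, (h + 1):n] <- f2
  m
}

# simulated diploid experiment: bipartite maternal, globular paternal
sim_diploid <- function(n_bins = 50, hinge = 20, depth = 2e4,
                        snp_rate = 0.3, dup_rate = 0.05, seed = 1L) {
  xi <- make_structure(n_bins, "bipartite", hinge_index = hinge, seed = seed)
  xa <- make_structure(n_bins, "globular", seed = seed + 1000L)
  mm <- simulate_contact_map(xi, alpha = -3, depth = depth,
                             seed = seed + 2000L)
  mp <- simulate_contact_map(xa, alpha = -3, depth = depth,
                             seed = seed + 3000L)
  mm$haplotype <- "maternal"; mp$haplotype <- "paternal"
  pairs <- simulate_pairs(list(maternal = mm, paternal = mp),
                          snp_informative_rate = snp_rate,
                          dup_rate = dup_rate, seed = seed + 4000L)
  list(xi = xi, xa = xa, true_maternal = mm, true_paternal = mp,
       pairs = pairs)
}

# brute-force bipartite index by nested loops (independent oracle)
bi_bruteforce <- function(m, h) {
  n <- nrow(m)
  s1 <- 0; s2 <- 0; si <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i <= h && j <= h) s1 <- s1 + m[i, j]
    if (i > h && j > h) s2 <- s2 + m[i, j]
    if (i <= h && j > h) si <- si + m[i, j]
  }
  (s1 / h^2 + s2 / (n - h)^2) / (2 * si / (h * (n - h)))
}
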