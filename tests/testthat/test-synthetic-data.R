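test_that("generated structures are centered, deterministic, and bipartite mode separates clusters", {
  g <- make_structure(50, "globular", seed = 1)
  expect_equal(dim(g$coords), c(50, 3))
  expect_lt(sqrt(sum(colMeans(g$coords)^2)), 1e-9)
  expect_identical(g$coords, make_structure(50, "globular", seed = 1)$coords)

  s <- make_structure(100, "bipartite", hinge_index = 30, seed = 7)
  cl <- ifelse(seq_len(100) < 30, 1L, ifelse(seq_len(100) > 30, 2L, NA))
  D <- as.matrix(dist(s$coords))
  within <- c(D[cl %in% 1, cl %in% 1][upper.tri(diag(sum(cl %in% 1)))],
              D[cl %in% 2, cl %in% 2][upper.tri(diag(sum(cl %in% 2)))])
  across <- D[which(cl %in% 1), which(cl %in% 2)]
  expect_lt(mean(within), mean(across))

  expect_error(make_structure(10, "bipartite", hinge_index = 10),
               "hinge_index")
  expect_error(make_structure(10, "bipartite"), "hinge_index")
})

test_that("simulated contact maps follow the distance-decay Poisson model", {
  s <- make_structure(40, "globular", seed = 2)
  m <- simulate_contact_map(s, alpha = -3, depth = 1e4, seed = 3)
  expect_lt(abs(map_total(m) - 1e4), 3 * sqrt(1e4))
  expect_identical(m$counts,
                   simulate_contact_map(s, alpha = -3, depth = 1e4,
                                        seed = 3)$counts)
  z <- simulate_contact_map(s, alpha = -3, depth = 0, seed = 4)
  expect_true(all(z$counts == 0))

  # rate ratio (2d/d)^-alpha = 8 for alpha = -3, averaged over replicates
  sq <- structure(list(coords = rbind(c(0, 0, 0), c(1, 0, 0),
                                      c(0, 50, 0), c(2, 50, 0)),
                       valid = rep(TRUE, 4), mode = "globular",
                       hinge_index = NULL), class = "structure3d")
  counts <- vapply(1:1000, function(i) {
    cm <- simulate_contact_map(sq, beta = 4, alpha = -3, seed = i)$counts
    c(cm[1, 2], cm[3, 4])
  }, numeric(2))
  expect_equal(mean(counts[1, ]) / mean(counts[2, ]), 8, tolerance = 0.15)

  co <- structure(list(coords = rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                                      c(2, 0, 0)),
                       valid = rep(TRUE, 4), mode = "globular",
                       hinge_index = NULL), class = "structure3d")
  expect_error(simulate_contact_map(co, depth = 10), "coincident beads")
})

test_that("simulated pairs carry SNP evidence at the configured rate and conserve contacts", {
  sim <- sim_diploid(n_bins = 30, hinge = 12, depth = 6000, snp_rate = 0.3,
                     dup_rate = 0, seed = 5)
  p <- sim$pairs
  n_true <- map_total(sim$true_maternal) + map_total(sim$true_paternal)
  expect_equal(nrow(p), n_true)   # conservation without duplicates
  frac_inf <- mean(p$allele1 != "." | p$allele2 != ".")
  expect_equal(frac_inf, 1 - 0.7^2, tolerance = 3 * sqrt(0.25 / nrow(p)) / 0.5)

  maps <- list(maternal = sim$true_maternal, paternal = sim$true_paternal)
  all_inf <- simulate_pairs(maps, snp_informative_rate = 1,
                            conflict_rate = 0, seed = 6)
  expect_true(all(all_inf$allele1 != "." | all_inf$allele2 != "."))
  none <- simulate_pairs(maps, snp_informative_rate = 0,
                         conflict_rate = 0, seed = 7)
  expect_true(all(none$allele1 == "." & none$allele2 == "."))
  expect_true(all(classify_pairs(none)$category == "uncertain"))

  expect_error(simulate_pairs(maps, snp_informative_rate = 2), "rates")
  expect_error(simulate_pairs(maps, dup_rate = 1), "rates")
})

test_that("duplicated pair records copy both end coordinates exactly", {
  sim <- sim_diploid(n_bins = 25, hinge = 10, depth = 4000,
                     dup_rate = 0.2, seed = 11)
  p <- sim$pairs
  dups <- p[grepl("^dup", p$read_id), ]
  expect_gt(nrow(dups), 0)
  key <- function(df) paste(df$chrom1, df$pos1, df$chrom2, df$pos2)
  expect_true(all(key(dups) %in% key(p[!grepl("^dup", p$read_id), ])))
})

test_that("planted feature tracks are exchangeable at zero bias and peripheral under bias", {
  s <- make_structure(80, "globular", seed = 3)
  r <- sqrt(rowSums(s$coords^2))
  expect_true(all(plant_features(s, 0, 0, seed = 1)$density == 0))
  rhos <- vapply(1:30, function(i)
    suppressWarnings(cor(plant_features(s, 400, 0, seed = i)$density, r,
                         method = "spearman")), numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
  rho5 <- cor(plant_features(s, 400, 5, seed = 4)$density, r,
              method = "spearman")
  expect_gt(rho5, 0.5)
})

test_that("gene tables place genes in distinct bins with the planted RNA bias", {
  bt <- make_bin_table(c(chr7 = 50e6, chrX = 50e6), 1e6)
  expect_equal(nrow(make_gene_table(bt, 0)), 0)
  expect_error(make_gene_table(bt, nrow(bt) + 1), "more genes than bins")

  g <- make_gene_table(bt, 60,
                       imprinted_spec = list(n_maternal = 20, n_paternal = 0,
                                             rna_multiplier = 10,
                                             contact_multiplier = 3),
                       escape_spec = list(n = 5, contact_multiplier = 2,
                                          polii_mean = 10),
                       n_reads = 100, seed = 9)
  expect_equal(nrow(g), 60)
  mid <- floor((g$start + g$end) / 2)
  bins <- floor(mid / 1e6) + ifelse(g$chrom == "chrX", 50, 0)
  expect_equal(anyDuplicated(bins), 0)
  im <- g[g$category == "imprinted-maternal", ]
  # expected maternal fraction 10/11 of 100 reads
  expect_equal(mean(im$rna_maternal), 100 * 10 / 11, tolerance = 0.05)
  expect_true(all(g$category[g$chrom != "chrX"] != "escape"))
})
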