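test_that("imprinted-gene selection applies the binomial test with the autosomal background proportion", {
  genes <- data.frame(
    id = c("a", "b", "c", "bg1", "bg2"),
    chrom = c("chr7", "chr7", "chr7", "chr2", "chr2"),
    start = c(1, 2, 3, 4, 5) * 1e5, end = c(1, 2, 3, 4, 5) * 1e5 + 1e4,
    strand = "+",
    category = c("imprinted-maternal", "imprinted-maternal",
                 "imprinted-paternal", "background-autosomal",
                 "background-autosomal"),
    rna_maternal = c(100, 5, 2, 50, 60),
    rna_paternal = c(0, 5, 98, 50, 60), stringsAsFactors = FALSE)
  sel <- select_imprinted(genes)
  expect_equal(attr(sel, "p0"), 0.5)
  expect_true("a" %in% sel$id)     # binomial tail 2^-100
  expect_true("c" %in% sel$id)     # paternal direction
  expect_false("b" %in% sel$id)    # 5/5 is null
  expect_equal(nrow(select_imprinted(genes[genes$category ==
                                             "background-autosomal", ])), 0)
  expect_error(select_imprinted(genes[1:3, ]), "empty autosomal background")
})

test_that("escape-gene selection thresholds mean promoter PolII occupancy inclusively", {
  g <- data.frame(id = c("e1", "e2", "e3"), chrom = "chrX",
                  start = c(1e6, 2e6, 3e6), end = c(1.1e6, 2.1e6, 3.1e6),
                  category = "escape", stringsAsFactors = FALSE)
  g$polii <- rbind(rep(5, 10), rep(0, 10), c(rep(0, 9), 50))
  sel <- select_escape(g, polii_min = 5)
  expect_equal(sel$id, c("e1", "e3"))   # mean 5 (boundary) and mean 5
  g2 <- g; g2$polii[1, 1] <- NA
  expect_warning(s2 <- select_escape(g2), "missing PolII")
  expect_equal(s2$id, "e3")
})

test_that("background construction excludes focal windows, collapses shared windows, and drops contactless genes", {
  bt <- make_bin_table(c(chr1 = 2e6), 4e4)
  n <- nrow(bt)
  cnt <- matrix(1, n, n)
  cnt[, 40] <- cnt[40, ] <- 0          # window with no contacts
  pooled <- contact_map(cnt, bt)
  genes <- data.frame(
    id = c("focal", "samewin", "w2a", "w2b", "w2c", "nocontact", "ok"),
    chrom = "chr1",
    start = c(10 * 4e4 + 100, 10 * 4e4 + 2e4, 20 * 4e4 + 300,
              20 * 4e4 + 100, 20 * 4e4 + 200, 39 * 4e4 + 10, 30 * 4e4),
    stringsAsFactors = FALSE)
  genes$end <- genes$start + 1000
  genes$category <- "background-autosomal"
  bg <- build_background(genes, "focal", pooled)$autosomal
  expect_false("samewin" %in% bg$id)         # shares the focal window
  expect_equal(sum(bg$id %in% c("w2a", "w2b", "w2c")), 1)
  expect_true("w2b" %in% bg$id)              # lowest start wins
  expect_false("nocontact" %in% bg$id)
  expect_true("ok" %in% bg$id)
})

test_that("virtual-4C log-ratios follow the pseudocount convention and are exactly antisymmetric", {
  bt <- make_bin_table(c(chr1 = 4e5), 4e4)
  g <- data.frame(id = "g", chrom = "chr1", start = 4e4, end = 8e4,
                  stringsAsFactors = FALSE)
  mk <- function(colsum) {
    m <- matrix(0, 10, 10)
    m[, 2] <- colsum / 10; m[2, ] <- colsum / 10
    m[2, 2] <- m[2, 2]  # symmetric by construction
    contact_map((m + t(m)) / 2, bt)
  }
  v1 <- virtual4c_ratio(mk(99), mk(9), g)
  expect_equal(v1$log_ratio, 1)
  expect_equal(virtual4c_ratio(mk(42), mk(42), g)$log_ratio, 0)
  expect_equal(virtual4c_ratio(mk(0), mk(999), g)$log_ratio, -3)
  out <- data.frame(id = "far", chrom = "chr1", start = 5e5, end = 6e5)
  expect_error(virtual4c_ratio(mk(1), mk(1), out), "outside")

  # antisymmetry on random maps, exact in floating point
  s <- make_structure(10, "globular", seed = 181)
  A <- simulate_contact_map(s, alpha = -3, depth = 5e3, seed = 182,
                            resolution = 4e4, chrom = "chr1")
  B <- simulate_contact_map(s, alpha = -3, depth = 5e3, seed = 183,
                            resolution = 4e4, chrom = "chr1")
  gs <- data.frame(id = sprintf("g%d", 1:5), chrom = "chr1",
                   start = (0:4) * 8e4 + 100, stringsAsFactors = FALSE)
  gs$end <- gs$start + 3e4
  expect_identical(virtual4c_ratio(A, B, gs)$log_ratio,
                   -virtual4c_ratio(B, A, gs)$log_ratio)
})

test_that("planted allelic contact multipliers are recovered in the median log-ratio", {
  bt <- make_bin_table(c(chr7 = 40e6), 4e4)
  s <- make_structure(nrow(bt), "globular", seed = 191)
  base <- simulate_contact_map(s, alpha = -3, depth = 3e5, seed = 192,
                               resolution = 4e4, chrom = "chr7")
  genes <- make_gene_table(bt, 40,
                           imprinted_spec = list(n_maternal = 15,
                                                 n_paternal = 0,
                                                 rna_multiplier = 10,
                                                 contact_multiplier = 3),
                           escape_spec = list(n = 0), seed = 193)
  mg <- genes[genes$category == "imprinted-maternal", ]
  matm <- plant_contact_bias(base, mg, rep(3, nrow(mg)), seed = 194)
  matm$haplotype <- "maternal"
  matp <- base
  matp$counts <- rpois_map(base$counts, 195)
  matp$haplotype <- "paternal"
  v <- virtual4c_ratio(matm, matp, mg)
  expect_equal(median(v$log_ratio), log10(3), tolerance = 0.15)
  # planted set deviates from background by KS and Wilcoxon
  bg <- genes[genes$category == "background-autosomal", ]
  vb <- virtual4c_ratio(matm, matp, bg)
  cmp <- compare_ratio_distributions(v$log_ratio, vb$log_ratio)
  expect_lt(cmp$ks_p, 0.01)
  expect_lt(cmp$wilcox_p, 0.01)
  expect_gt(cmp$median_shift, 0.3)
  expect_false(cmp$unreliable)
})

test_that("ratio-distribution comparison handles identical and tiny samples", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  same <- compare_ratio_distributions(x, x)
  expect_equal(same$ks_statistic, 0)
  expect_equal(same$ks_p, 1)
  tiny <- compare_ratio_distributions(c(1, 2), x)
  expect_true(tiny$unreliable)
  expect_error(compare_ratio_distributions(numeric(0), x), "non-empty")
})
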