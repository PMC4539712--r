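test_that("superdomain centers are the exact centroids excluding the hinge bead", {
  coords <- rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  st <- structure(list(coords = coords, valid = rep(TRUE, 4),
                       mode = NULL, hinge_index = NULL),
                  class = "structure3d")
  ctr <- superdomain_centers(st, 2)
  expect_equal(ctr$c1, c(-1, 0, 0))           # bead 1 only
  expect_equal(ctr$c2, c(1, 0.5, 0))          # beads 3 and 4
  expect_error(superdomain_centers(st, 1), "empty superdomain")

  # mirror-symmetric structure: c1 = -c2
  n <- 21
  sym <- structure(list(coords = cbind(seq(-10, 10), 0, 0),
                        valid = rep(TRUE, n), mode = NULL,
                        hinge_index = NULL), class = "structure3d")
  cs <- superdomain_centers(sym, 11)
  expect_equal(cs$c1, -cs$c2, tolerance = 1e-9)

  # centroid decomposition: bead-weighted recombination returns the origin
  s <- make_structure(60, "bipartite", hinge_index = 25, seed = 161)
  c2r <- superdomain_centers(s, 25)
  rec <- (24 * c2r$c1 + 35 * c2r$c2 + s$coords[25, ]) / 60
  expect_equal(unname(rec), c(0, 0, 0), tolerance = 1e-9)
})

test_that("gene radial distances use the midpoint bin with half-open convention", {
  bt <- make_bin_table(c(chrX = 10e6), 1e6)
  coords <- matrix(0, 10, 3); coords[4, ] <- c(3, 4, 0)
  st <- structure(list(coords = coords, valid = rep(TRUE, 10),
                       mode = NULL, hinge_index = NULL),
                  class = "structure3d")
  g <- data.frame(id = "g1", chrom = "chrX", start = 3.2e6, end = 3.8e6)
  rd <- gene_radial_distance(g, st, bt)
  expect_equal(rd$bin, 4L)
  expect_equal(rd$d_center, 5)
  # midpoint exactly on a bin edge goes to the higher-index bin
  ge <- data.frame(id = "g2", chrom = "chrX", start = 3.9e6, end = 4.1e6)
  expect_equal(gene_radial_distance(ge, st, bt)$bin, 5L)

  # brute-force oracle on a 10-gene fixture
  s <- make_structure(10, "globular", seed = 162)
  ctr <- list(c1 = c(1, 0, 0), c2 = c(-1, 0, 0), h = 5)
  set.seed(163)
  gs <- data.frame(id = sprintf("g%d", 1:10), chrom = "chrX",
                   start = runif(10, 0, 9.5e6))
  gs$end <- gs$start + 2e5
  rd <- gene_radial_distance(gs, s, bt, ctr)
  for (r in 1:10) {
    k <- floor(floor((gs$start[r] + gs$end[r]) / 2) / 1e6) + 1
    x <- s$coords[k, ]
    expect_equal(rd$bin[r], k)
    expect_equal(rd$d_center[r], sqrt(sum(x^2)))
    expect_equal(rd$d_c1[r], sqrt(sum((x - ctr$c1)^2)))
    expect_equal(rd$d_c2[r], sqrt(sum((x - ctr$c2)^2)))
  }

  # masked midpoint bin falls back to the nearest valid bead, flagged
  s$valid[4] <- FALSE
  rdm <- gene_radial_distance(g, s, bt)
  expect_true(rdm$flagged)
  expect_true(rdm$bin %in% c(3L, 5L))
})

test_that("periphery Z-test flags planted peripheral sets and stays near null otherwise", {
  s <- make_structure(300, "globular", seed = 171)
  r <- sqrt(rowSums(s$coords^2))
  top <- order(r, decreasing = TRUE)[1:30]
  hit <- vapply(1:20, function(i)
    periphery_ztest(r[top], r[-top], n_sample = 30, n_reps = 300,
                    seed = i)$p_value < 0.05, logical(1))
  expect_gte(mean(hit), 0.9)
  # observed mean equal to the null mean gives z near 0, p near 0.5
  zt <- periphery_ztest(rep(mean(r), 5), r, n_sample = 50, n_reps = 2000,
                        seed = 3)
  expect_lt(abs(zt$z), 0.1)
  expect_equal(zt$p_value, 0.5, tolerance = 0.05)
  expect_error(periphery_ztest(numeric(0), r), "focal set is empty")
})

test_that("feature periphery analysis partitions quartiles and detects planted bias", {
  st <- structure(list(coords = cbind(c(1, 2, 3, 4), 0, 0),
                       valid = rep(TRUE, 4), mode = NULL,
                       hinge_index = NULL), class = "structure3d")
  tr <- data.frame(bin = 1:4, density = c(1, 2, 3, 4))
  fa <- feature_periphery_analysis(tr, st, mode = "xa")
  expect_equal(fa$rich, 4L)
  expect_equal(fa$poor, 1L)

  cst <- data.frame(bin = 1:4, density = rep(2, 4))
  fc <- feature_periphery_analysis(cst, st, mode = "xa")
  expect_true(fc$degenerate)
  expect_equal(fc$p_value, 1)

  s <- make_structure(100, "bipartite", hinge_index = 40, seed = 172)
  ctr <- superdomain_centers(s, 40)
  cen <- rbind(ctr$c1, ctr$c2)
  p5 <- feature_periphery_analysis(
    plant_features(s, 500, 5, seed = 1, centers = cen), s, h = 40,
    mode = "xi")
  expect_lt(p5$p_value, 0.01)
  expect_equal(class(p5$ecdf_rich), c("ecdf", "stepfun", "function"))
})
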