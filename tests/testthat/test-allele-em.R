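test_that("group keys pool bin pairs by chromosome-haplotype and distance", {
  expect_equal(group_id("chr1", "chr1", "M", 3, 10), "chr1M:d7")
  expect_equal(group_id("chr1", "chr2", "M", 3, 10), "chr1M|chr2M")
  expect_equal(group_id("chr2", "chr1", "M", 10, 3),
               group_id("chr1", "chr2", "M", 3, 10))
  expect_equal(group_id("chr1", "chr1", "P", 10, 3),
               group_id("chr1", "chr1", "P", 3, 10))
})

test_that("distance groups merge adjacent distances to reach the observation floor", {
  g <- make_distance_groups(200, min_obs = 50)
  counts <- tapply(200 - (0:199), g, sum)
  expect_true(all(counts >= 50))
  expect_true(all(diff(g) >= 0))   # groups are contiguous in distance
  # coarse case: plenty of pairs per distance keeps groups near-singleton
  g1 <- make_distance_groups(200, min_obs = 1)
  expect_equal(length(unique(g1)), 200)
})

test_that("moment estimation of Gamma hyperparameters matches hand algebra and recovers truth", {
  fit <- fit_gamma_hyperparams(c(0, 4, 8))
  expect_equal(unname(fit["beta"]), 0.6)
  expect_equal(unname(fit["alpha"]), 2.4)
  expect_false(attr(fit, "fallback"))

  fb <- fit_gamma_hyperparams(c(2, 2, 2))
  expect_true(attr(fb, "fallback"))
  expect_equal(unname(fb["alpha"] / fb["beta"]), 2)

  set.seed(61)
  lam <- rgamma(1e5, shape = 2, rate = 0.5)
  x <- rpois(1e5, lam)
  rec <- fit_gamma_hyperparams(x)
  expect_equal(unname(rec["alpha"]), 2, tolerance = 0.1)
  expect_equal(unname(rec["beta"]), 0.5, tolerance = 0.1)
})

test_that("posterior mean follows Gamma-Poisson conjugacy", {
  expect_equal(posterior_mean(5, 1, 1), 3)
  expect_equal(posterior_mean(0, 2, 3), 0.5)
  # numeric-integration oracle for the conjugate closed form
  post_num <- function(x, a, b) {
    f <- function(l) l^(a + x - 1) * exp(-(b + 1) * l)
    integrate(function(l) l * f(l), 0, Inf)$value /
      integrate(f, 0, Inf)$value
  }
  for (case in list(c(5, 1, 1), c(0, 2, 3), c(7, 2.4, 0.6))) {
    expect_equal(posterior_mean(case[1], case[2], case[3]),
                 post_num(case[1], case[2], case[3]), tolerance = 1e-6)
  }
  # beta -> Inf limit: posterior mean approaches the prior mean alpha/beta
  expect_equal(posterior_mean(5, 2e8, 1e8), 2, tolerance = 1e-6)
  expect_error(posterior_mean(-1, 1, 1), "non-negative")
})

test_that("EM distributes uncertain mass with posterior-mean weights and conserves mass", {
  sim <- sim_diploid(n_bins = 40, hinge = 15, depth = 1.5e4, snp_rate = 0.3,
                     dup_rate = 0, seed = 71)
  seg <- segregate_pairs(sim$pairs)
  maps <- bin_pairs(seg$pairs, sim$true_maternal$bins)
  em <- em_assign_uncertain(maps[c("maternal", "paternal")], maps$uncertain,
                            max_iter = 100)
  expect_true(em$state$converged)
  total_in <- map_total(maps$maternal) + map_total(maps$paternal) +
    map_total(maps$uncertain)
  expect_equal(map_total(em$maternal) + map_total(em$paternal), total_in,
               tolerance = 1e-6 / max(total_in, 1))
  w <- em$state$weights
  expect_true(all(w$weight_maternal >= 0 & w$weight_maternal <= 1))
  # fixed point: converged weights equal the posterior-mean ratio
  # recomputed from the final fractional maps with per-distance refits
  n <- nrow(em$maternal$counts)
  dg <- make_distance_groups(n, 50)
  act <- which(w$uncertain > 0)
  lam <- function(map, i, j) {
    d <- abs(w$i - w$j)
    grp <- dg[d + 1]
    cells <- grp == grp[match(TRUE, w$i == i & w$j == j)]
    hp <- fit_gamma_hyperparams(map$counts[cbind(w$i[cells], w$j[cells])])
    posterior_mean(map$counts[i, j], hp["alpha"], hp["beta"])
  }
  for (r in utils::head(act, 5)) {
    lm <- lam(em$maternal, w$i[r], w$j[r])
    lp <- lam(em$paternal, w$i[r], w$j[r])
    expect_equal(unname(w$weight_maternal[r]), unname(lm / (lm + lp)),
                 tolerance = 0.02)
  }

  # zero uncertain pairs: output equals input exactly
  zero_u <- maps$uncertain
  zero_u$counts[] <- 0
  em0 <- em_assign_uncertain(maps[c("maternal", "paternal")], zero_u)
  expect_equal(em0$maternal$counts, maps$maternal$counts)
  expect_equal(em0$paternal$counts, maps$paternal$counts)

  # no certain counts: unidentifiable
  none <- maps
  none$maternal$counts[] <- 0
  none$paternal$counts[] <- 0
  expect_error(em_assign_uncertain(none[c("maternal", "paternal")],
                                   maps$uncertain), "unidentifiable")
})

test_that("EM induces no spurious allelic skew when the haplotype maps are identical", {
  s <- make_structure(40, "globular", seed = 81)
  m1 <- simulate_contact_map(s, alpha = -3, depth = 4e4, seed = 82)
  m2 <- simulate_contact_map(s, alpha = -3, depth = 4e4, seed = 83)
  m1$haplotype <- "maternal"; m2$haplotype <- "paternal"
  pairs <- simulate_pairs(list(maternal = m1, paternal = m2),
                          snp_informative_rate = 0.3, dup_rate = 0,
                          conflict_rate = 0, seed = 84)
  seg <- segregate_pairs(pairs)
  maps <- bin_pairs(seg$pairs, m1$bins)
  em <- em_assign_uncertain(maps[c("maternal", "paternal")], maps$uncertain,
                            max_iter = 100)
  ut <- upper.tri(m1$counts, diag = TRUE)
  skew <- mean(abs(em$maternal$counts[ut] - em$paternal$counts[ut]))
  scale <- mean((em$maternal$counts[ut] + em$paternal$counts[ut]) / 2)
  expect_lt(skew / scale, 1.5)  # per-cell skew stays at sampling-noise scale
  total_skew <- abs(map_total(em$maternal) - map_total(em$paternal)) /
    (map_total(em$maternal) + map_total(em$paternal))
  expect_lt(total_skew, 0.02)
})
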