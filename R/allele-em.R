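# Empirical-Bayes EM assignment of allele-uncertain contacts.
#
# Model: observed allele-specific counts X ~ Poisson(lambda) with a
# Gamma(alpha_G, beta_G) prior on lambda whose hyperparameters are shared
# within genomic groups G: intrachromosomal bin pairs of one
# chromosome-haplotype at the same (binned) genomic distance share a
# group, and interchromosomal pairs share a group per chromosome pair.
# Uncertain contacts in pooled coordinates are distributed over their
# candidate diploid assignments with weights proportional to the current
# posterior-mean rates, iterating hyperparameter refits to convergence.

#' Genomic group key of a diploid bin pair
#'
#' Same chromosome and haplotype on both ends gives an intrachromosomal
#' key `"<chrom><hap>:d<distance>"` (distance in bins, optionally pooled
#' by a distance-group map); different chromosomes give a canonically
#' ordered interchromosomal key.
#'
#' @param chrom_i,chrom_j chromosome names.
#' @param hap haplotype label shared by both ends (cis candidates).
#' @param i,j bin indices within their chromosomes.
#' @param dist_group optional integer vector mapping bin distance `d` to a
#'   pooled group label via `dist_group[d + 1]`.
#' @return character key, symmetric in its ends.
#' @export
group_id <- function(chrom_i, chrom_j, hap, i, j, dist_group = NULL) {
  intra <- chrom_i == chrom_j
  d <- abs(i - j)
  dg <- if (is.null(dist_group)) d else dist_group[d + 1]
  k1 <- pmin(chrom_i, chrom_j); k2 <- pmax(chrom_i, chrom_j)
  ifelse(intra, paste0(chrom_i, hap, ":d", dg),
         paste0(k1, hap, "|", k2, hap))
}

#' Pool bin distances into groups with enough observations
#'
#' At coarse resolution every integer bin distance is its own group; at
#' finer resolutions adjacent distances are merged (from the largest
#' distance down) until each group contains at least `min_obs` bin pairs
#' on a chromosome of `n` bins (there are `n - d` pairs at distance `d`).
#'
#' @param n number of bins on the chromosome.
#' @param min_obs minimum bin pairs per group (default 50).
#' @return integer vector `g` of length `n` with `g[d + 1]` the group
#'   label of distance `d`.
#' @export
make_distance_groups <- function(n, min_obs = 50) {
  d <- 0:(n - 1)
  count <- n - d
  g <- integer(n)
  cur <- 0L; acc <- 0
  for (k in seq_len(n)) {            # d = k - 1, small d first
    if (acc >= min_obs) { cur <- cur + 1L; acc <- 0 }
    g[k] <- cur
    acc <- acc + count[k]
  }
  # merge a trailing underfull group into its neighbour
  if (acc < min_obs && cur > 0) g[g == cur] <- cur - 1L
  g
}

#' Method-of-moments Gamma hyperparameters for a count group
#'
#' Matches the Gamma-Poisson marginal moments: with group mean `m` and
#' population variance `v`, `beta = m / (v - m)` and `alpha = m * beta`
#' when `v > m > 0`. When the counts are under-dispersed (`v <= m`) the
#' prior degenerates toward a point mass and a near-Poisson fallback is
#' used (`beta = 1e3`, `alpha = m * beta`); an all-zero group uses a
#' configurable mean floor.
#'
#' @param x numeric vector of (possibly fractional) counts.
#' @param fallback_beta prior precision used when moment matching
#'   degenerates.
#' @param mean_floor prior mean used when the group mean is zero.
#' @return named numeric vector `c(alpha, beta)` with attribute
#'   `fallback`.
#' @export
fit_gamma_hyperparams <- function(x, fallback_beta = 1e3,
                                  mean_floor = 1e-6) {
  stopifnot(length(x) > 0)
  m <- mean(x)
  v <- mean((x - m)^2)               # population variance
  if (v > m && m > 0) {
    beta <- m / (v - m)
    alpha <- m * beta
    fb <- FALSE
  } else {
    beta <- fallback_beta
    alpha <- max(m, mean_floor) * beta
    fb <- TRUE
  }
  structure(c(alpha = alpha, beta = beta), fallback = fb)
}

#' Posterior mean of a Poisson rate under a Gamma prior
#'
#' Gamma-Poisson conjugacy: observing count `x` under a
#' `Gamma(alpha, beta)` prior (rate parameterization) gives posterior
#' mean `(alpha + x) / (beta + 1)`.
#'
#' @param x observed count (>= 0); vectorized.
#' @param alpha,beta prior hyperparameters (> 0).
#' @return posterior mean rate(s).
#' @export
posterior_mean <- function(x, alpha, beta) {
  if (any(x < 0)) stop("counts must be non-negative")
  stopifnot(all(alpha > 0), all(beta > 0))
  (alpha + x) / (beta + 1)
}

#' EM assignment of allele-uncertain contacts to diploid maps
#'
#' Distributes each uncertain contact at pooled bins (i, j) fractionally
#' over its candidate diploid assignments -- the maternal and paternal
#' cis placements at the same coordinates -- with weights proportional to
#' the current posterior-mean rates of the candidates. Hyperparameters
#' are refit each iteration from the current fractional maps, per
#' distance group and haplotype. Iteration stops when the largest
#' absolute weight change falls below `tol` or at `max_iter`.
#'
#' @param certain named list with `maternal` and `paternal`
#'   `contact_map`s of allele-certain counts.
#' @param uncertain `contact_map` of allele-uncertain counts in pooled
#'   coordinates, sharing the bin table.
#' @param tol convergence tolerance on assignment weights (default 1e-3).
#' @param max_iter maximum EM iterations (default 50).
#' @param min_obs minimum bin pairs per distance group (default 50).
#' @param pseudocount initialization pseudocount guarding zero-locking.
#' @return list with `maternal` and `paternal` inferred `contact_map`s
#'   (fractional counts, labels `inferred-*`) and `state` (weights
#'   matrix, iterations, converged flag, weight-change trace).
#' @export
em_assign_uncertain <- function(certain, uncertain, tol = 1e-3,
                                max_iter = 50, min_obs = 50,
                                pseudocount = 0.5) {
  cm <- certain$maternal$counts
  cp <- certain$paternal$counts
  u <- uncertain$counts
  if (!all(dim(cm) == dim(u)) || !all(dim(cp) == dim(u)))
    stop("maps must share a bin table")
  if (sum(cm) + sum(cp) == 0)
    stop("no allele-certain counts: model unidentifiable")
  n <- nrow(u)
  bins <- certain$maternal$bins
  chrom_of <- bins$chrom
  # per-chromosome distance-group lookups
  chroms <- unique(chrom_of)
  dgroups <- lapply(chroms, function(ch)
    make_distance_groups(sum(chrom_of == ch), min_obs))
  names(dgroups) <- chroms
  # group key per upper-triangle cell (haplotype added per map)
  ut <- which(upper.tri(u, diag = TRUE), arr.ind = TRUE)
  ci <- chrom_of[ut[, 1]]; cj <- chrom_of[ut[, 2]]
  offs <- vapply(chroms, function(ch) min(bins$bin[bins$chrom == ch]),
                 numeric(1))
  within_i <- ut[, 1] - offs[match(ci, chroms)] + 1
  within_j <- ut[, 2] - offs[match(cj, chroms)] + 1
  dist_lab <- rep(NA_integer_, nrow(ut))
  intra <- ci == cj
  if (any(intra)) {
    d <- abs(within_i - within_j)
    for (ch in chroms) {
      sel <- intra & ci == ch
      dist_lab[sel] <- dgroups[[ch]][d[sel] + 1]
    }
  }
  key <- ifelse(ci == cj, paste0(ci, ":d", dist_lab),
                paste0(pmin(ci, cj), "|", pmax(ci, cj)))
  gid <- factor(key)
  uvals <- u[ut]
  active <- uvals > 0
  # initial weights from certain counts with a pseudocount
  w <- (cm[ut] + pseudocount) / (cm[ut] + cp[ut] + 2 * pseudocount)
  it <- 0; converged <- FALSE; trace <- numeric(0)
  hyper <- NULL
  while (it < max_iter) {
    it <- it + 1
    fm <- cm[ut] + w * uvals
    fp <- cp[ut] + (1 - w) * uvals
    hm <- vapply(split(fm, gid), function(x)
      unclass(fit_gamma_hyperparams(x)), numeric(2))
    hp <- vapply(split(fp, gid), function(x)
      unclass(fit_gamma_hyperparams(x)), numeric(2))
    g <- as.integer(gid)
    lam_m <- posterior_mean(fm, hm[1, g], hm[2, g])
    lam_p <- posterior_mean(fp, hp[1, g], hp[2, g])
    w_new <- w
    w_new[active] <- (lam_m / (lam_m + lam_p))[active]
    delta <- if (any(active)) max(abs(w_new - w)[active]) else 0
    trace <- c(trace, delta)
    w <- w_new
    hyper <- list(maternal = hm, paternal = hp,
                  groups = levels(gid))
    if (delta < tol) { converged <- TRUE; break }
  }
  build <- function(cert, wv, label) {
    m <- matrix(0, n, n)
    m[ut] <- cert[ut] + wv * uvals
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    contact_map(m, bins, haplotype = label)
  }
  list(maternal = build(cm, w, "inferred-maternal"),
       paternal = build(cp, 1 - w, "inferred-paternal"),
       state = list(weights = data.frame(i = ut[, 1], j = ut[, 2],
                                         weight_maternal = w,
                                         uncertain = uvals),
                    iterations = it, converged = converged,
                    delta_trace = trace, hyperparams = hyper))
}
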