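# Radial geometry of genes and 1D features within an inferred 3D
# structure: superdomain centers, radial distances, periphery Z-test,
# and feature-density periphery analysis.

#' Centroids of the two superdomains of a bipartite structure
#'
#' `c1` is the centroid of valid beads with index below the hinge and
#' `c2` of those above it; the hinge bead belongs to neither. The
#' chromosome center is the origin (structures are centered).
#'
#' @param struct a centered `structure3d`.
#' @param h hinge bead index, `0 < h < n`.
#' @return list with `c1`, `c2` (3-vectors) and `h`.
#' @export
superdomain_centers <- function(struct, h) {
  n <- nrow(struct$coords)
  if (h <= 0 || h >= n) stop("h must lie strictly inside (0, n)")
  low <- which(struct$valid & seq_len(n) < h)
  high <- which(struct$valid & seq_len(n) > h)
  if (length(low) == 0 || length(high) == 0)
    stop("empty superdomain at h = ", h)
  list(c1 = colMeans(struct$coords[low, , drop = FALSE]),
       c2 = colMeans(struct$coords[high, , drop = FALSE]),
       h = h)
}

#' Radial distances of genes within a structure
#'
#' For each gene, `k` is the bin containing the gene midpoint (half-open
#' bins, so a midpoint on a bin edge belongs to the higher-index bin).
#' Returns the distance of bead `k` to the chromosome center (the
#' origin), to each superdomain center when centers are supplied, and
#' the superdomain containing `k`. Genes whose midpoint bin is masked
#' use the nearest valid bead and are flagged.
#'
#' @param genes gene table rows (`chrom`, `start`, `end`).
#' @param struct a `structure3d`.
#' @param bin_table bin table aligned to the structure.
#' @param centers optional result of [superdomain_centers()].
#' @return data.frame with `id`, `bin`, `d_center`, `d_c1`, `d_c2`,
#'   `superdomain`, `d_own_center`, `flagged`.
#' @export
gene_radial_distance <- function(genes, struct, bin_table, centers = NULL) {
  mid <- floor((genes$start + genes$end) / 2)
  k <- pos_to_bin(genes$chrom, mid, bin_table)
  flagged <- !struct$valid[k]
  if (any(flagged)) {
    vidx <- which(struct$valid)
    k[flagged] <- vapply(k[flagged], function(b)
      vidx[which.min(abs(vidx - b))], integer(1))
  }
  x <- struct$coords[k, , drop = FALSE]
  d_center <- sqrt(rowSums(x^2))
  out <- data.frame(id = if (!is.null(genes$id)) genes$id
                         else seq_len(nrow(genes)),
                    bin = k, d_center = d_center,
                    flagged = flagged, stringsAsFactors = FALSE)
  if (!is.null(centers)) {
    out$d_c1 <- sqrt(rowSums(sweep(x, 2, centers$c1)^2))
    out$d_c2 <- sqrt(rowSums(sweep(x, 2, centers$c2)^2))
    out$superdomain <- ifelse(k < centers$h, 1L,
                              ifelse(k > centers$h, 2L, NA_integer_))
    out$d_own_center <- ifelse(!is.na(out$superdomain) &
                                 out$superdomain == 1L,
                               out$d_c1, out$d_c2)
  }
  out
}

#' Periphery enrichment Z-test for a focal gene set
#'
#' The null distribution of the expected distance is estimated by
#' repeatedly sampling `n_sample` genes from the background pool and
#' recording the sample mean distance; the observed mean distance of the
#' focal genes is compared by a one-sided Z-test for the peripheral
#' (greater-distance) alternative.
#'
#' @param focal_dist distances of the focal genes.
#' @param pool_dist distances of the background pool (excluding the
#'   focal genes).
#' @param n_sample genes drawn per resample (default 100, capped at the
#'   pool size).
#' @param n_reps resamples used to estimate the null (default 1000).
#' @param seed integer RNG seed.
#' @return list with `observed`, `null_mean`, `null_sd`, `z`, `p_value`,
#'   `n_focal`, `n_sample`, `n_reps`.
#' @export
periphery_ztest <- function(focal_dist, pool_dist, n_sample = 100,
                            n_reps = 1000, seed = 1L) {
  if (length(focal_dist) == 0) stop("focal set is empty")
  n_sample <- min(n_sample, length(pool_dist))
  if (n_sample < 1) stop("background pool is empty")
  set.seed(seed)
  null_means <- vapply(seq_len(n_reps), function(i)
    mean(sample(pool_dist, n_sample)), numeric(1))
  mu <- mean(null_means); sdv <- stats::sd(null_means)
  obs <- mean(focal_dist)
  z <- (obs - mu) / sdv
  list(observed = obs, null_mean = mu, null_sd = sdv, z = z,
       p_value = stats::pnorm(z, lower.tail = FALSE),
       n_focal = length(focal_dist), n_sample = n_sample, n_reps = n_reps)
}

#' Feature-density periphery analysis
#'
#' Computes each valid bin's radial distance -- to its own superdomain
#' center in `"xi"` mode (bins below the hinge use `c1`, above use `c2`,
#' the hinge bin its nearer center) or to the chromosome center in
#' `"xa"` mode -- partitions bins into feature-rich (top 25 % of
#' density, ties included) and feature-poor (bottom 25 %), and compares
#' the distance distributions with a one-sided Wilcoxon rank-sum test
#' for rich-more-peripheral. Both empirical CDFs are returned.
#'
#' @param track data.frame with `bin` and `density`, aligned to the
#'   structure's bins.
#' @param struct a `structure3d`.
#' @param h hinge index, required in `"xi"` mode.
#' @param mode `"xi"` (superdomain centers) or `"xa"` (chromosome
#'   center).
#' @param quantile_frac quantile defining rich/poor (default 0.25).
#' @return list with `table` (per-bin density and distance), `rich`,
#'   `poor` (bin indices), `ecdf_rich`, `ecdf_poor`, `p_value`,
#'   `degenerate` flag.
#' @export
feature_periphery_analysis <- function(track, struct, h = NULL,
                                       mode = c("xi", "xa"),
                                       quantile_frac = 0.25) {
  mode <- match.arg(mode)
  n <- nrow(struct$coords)
  stopifnot(nrow(track) == n)
  valid <- struct$valid
  if (mode == "xi") {
    if (is.null(h)) stop("xi mode requires the hinge index h")
    ctr <- superdomain_centers(struct, h)
    d1 <- sqrt(rowSums(sweep(struct$coords, 2, ctr$c1)^2))
    d2 <- sqrt(rowSums(sweep(struct$coords, 2, ctr$c2)^2))
    dist <- ifelse(seq_len(n) < h, d1, ifelse(seq_len(n) > h, d2,
                                              pmin(d1, d2)))
  } else {
    dist <- sqrt(rowSums(struct$coords^2))
  }
  tab <- data.frame(bin = track$bin, density = track$density,
                    distance = dist, valid = valid)
  vt <- tab[valid, ]
  k <- ceiling(quantile_frac * nrow(vt))
  dens_sorted <- sort(vt$density)
  lo_thr <- dens_sorted[k]
  hi_thr <- sort(vt$density, decreasing = TRUE)[k]
  degenerate <- lo_thr == hi_thr
  rich <- vt$bin[vt$density >= hi_thr]
  poor <- vt$bin[vt$density <= lo_thr]
  if (degenerate) {
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(vt$distance[vt$bin %in% rich],
                         vt$distance[vt$bin %in% poor],
                         alternative = "greater"))$p.value
  }
  list(table = tab, rich = rich, poor = poor,
       ecdf_rich = stats::ecdf(vt$distance[vt$bin %in% rich]),
       ecdf_poor = stats::ecdf(vt$distance[vt$bin %in% poor]),
       p_value = p, degenerate = degenerate,
       n_rich = length(rich), n_poor = length(poor))
}
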