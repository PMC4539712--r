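# Seeded generators for diploid Hi-C inputs: bead structures, Poisson
# contact maps, pair records with per-end SNP evidence, planted feature
# tracks and gene tables. These define the study conditions every
# downstream stage is tested against.

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic diploid Hi-C generator. Defaults
#' emulate an F1-hybrid experiment: a distance-decay exponent of -3, about
#' half of read pairs carrying at least one diagnostic SNP
#' (`snp_informative_rate` is per end), a few percent PCR duplicates, and a
#' small rate of conflicting SNP evidence.
#'
#' @param n_bins beads (bins) per homolog; at least 4.
#' @param resolution bp per bin.
#' @param hinge_index planted superdomain boundary bin (NULL for a
#'   non-bipartite homolog); must satisfy `0 < h < n_bins`.
#' @param alpha distance-decay exponent (negative; default -3).
#' @param beta contact-scale coefficient; ignored when `depth` is given.
#' @param depth total expected simulated pair count per homolog.
#' @param snp_informative_rate probability that a read end carries a
#'   diagnostic SNP.
#' @param dup_rate fraction of pairs duplicated by PCR.
#' @param conflict_rate rate of pairs with conflicting SNP evidence.
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_bins = 100, resolution = 1e6, hinge_index = NULL,
                       alpha = -3, beta = 1, depth = 1e5,
                       snp_informative_rate = 0.3, dup_rate = 0.05,
                       conflict_rate = 0.005, seed = 1L) {
  stopifnot(n_bins >= 4, snp_informative_rate > 0 || snp_informative_rate == 0,
            snp_informative_rate <= 1, dup_rate >= 0, dup_rate < 1,
            conflict_rate >= 0, conflict_rate < 1, alpha < 0, depth >= 0)
  if (!is.null(hinge_index) &&
      (hinge_index <= 0 || hinge_index >= n_bins))
    stop("hinge_index must lie strictly inside (0, n_bins)")
  structure(list(n_bins = n_bins, resolution = resolution,
                 hinge_index = hinge_index, alpha = alpha, beta = beta,
                 depth = depth, snp_informative_rate = snp_informative_rate,
                 dup_rate = dup_rate, conflict_rate = conflict_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a beads-on-a-string 3D structure
#'
#' Builds a confined random walk with near-unit consecutive-bead spacing.
#' In `"globular"` mode the walk is attracted to a single center. In
#' `"bipartite"` mode beads below the hinge form a confined walk around
#' one cluster center and beads above it around a second center placed
#' two cluster radii away; the hinge bead sits at the gap midpoint, so
#' the two compact superdomain-like clusters are joined at the hinge and
#' only the two hinge-adjacent bonds exceed the backbone length (the
#' hinge is a region of no contact between the clusters). Coordinates
#' are centered at the origin.
#'
#' @param n_bins number of beads (>= 4).
#' @param mode `"globular"` or `"bipartite"`.
#' @param hinge_index boundary bead for bipartite mode (`0 < h < n_bins`).
#' @param seed integer RNG seed.
#' @param cluster_radius target cluster radius in bead units.
#' @return a `structure3d`: list with `coords` (n x 3), `valid`, `mode`,
#'   `hinge_index`.
#' @export
make_structure <- function(n_bins, mode = c("globular", "bipartite"),
                           hinge_index = NULL, seed = 1L,
                           cluster_radius = 2.5) {
  mode <- match.arg(mode)
  stopifnot(n_bins >= 4)
  if (mode == "bipartite") {
    if (is.null(hinge_index))
      stop("bipartite mode requires a hinge_index")
    if (hinge_index <= 0 || hinge_index >= n_bins)
      stop("hinge_index must lie strictly inside (0, n_bins)")
  } else if (!is.null(hinge_index)) {
    stop("hinge_index is only meaningful in bipartite mode")
  }
  set.seed(seed)
  drift <- 1.7 / cluster_radius   # stationary radius ~ cluster_radius
  confined_walk <- function(n, center, start) {
    w <- matrix(0, n, 3)
    w[1, ] <- start
    if (n > 1) for (i in 2:n) {
      dir <- drift * (center - w[i - 1, ]) + stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      step <- abs(stats::rnorm(1, mean = 1, sd = 0.1))
      w[i, ] <- w[i - 1, ] + step * dir
    }
    w
  }
  if (mode == "globular") {
    coords <- confined_walk(n_bins, c(0, 0, 0),
                            stats::rnorm(3, sd = cluster_radius / 2))
  } else {
    sep <- 2 * cluster_radius
    c1 <- c(-sep / 2, 0, 0); c2 <- c(sep / 2, 0, 0)
    coords <- rbind(
      confined_walk(hinge_index - 1, c1, c1 + stats::rnorm(3, sd = 0.5)),
      matrix(stats::rnorm(3, sd = 0.2), 1, 3),          # hinge bead at gap
      confined_walk(n_bins - hinge_index, c2,
                    c2 + stats::rnorm(3, sd = 0.5)))
  }
  coords <- sweep(coords, 2, colMeans(coords))
  structure(list(coords = coords, valid = rep(TRUE, n_bins), mode = mode,
                 hinge_index = hinge_index),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d beads (%d invalid), mode %s\n",
              nrow(x$coords), sum(!x$valid),
              if (is.null(x$mode)) "inferred" else x$mode))
  invisible(x)
}

#' Simulate a contact map from a 3D structure
#'
#' Draws independent Poisson counts for each bead pair with rate
#' `beta * d_ij^alpha` (mirrored to the lower triangle). When `depth` is
#' given, `beta` is set so the expected total count equals `depth`.
#'
#' @param struct a `structure3d`.
#' @param beta contact scale (> 0); overridden when `depth` is supplied.
#' @param alpha distance-decay exponent (< 0; default -3).
#' @param depth expected total pair count, or NULL to use `beta`.
#' @param seed integer RNG seed.
#' @param resolution bp per bin for the emitted bin table.
#' @param chrom chromosome name for the bin table.
#' @return a `contact_map` with attribute `beta` (the scale used).
#' @export
simulate_contact_map <- function(struct, beta = 1, alpha = -3, depth = NULL,
                                 seed = 1L, resolution = 1e6,
                                 chrom = "chrX") {
  stopifnot(inherits(struct, "structure3d"), alpha < 0)
  n <- nrow(struct$coords)
  d <- as.matrix(stats::dist(struct$coords))
  ut <- upper.tri(d)
  if (any(d[ut] == 0)) {
    bad <- which(d == 0 & ut, arr.ind = TRUE)[1, ]
    stop(sprintf("coincident beads %d and %d (zero distance)",
                 bad[1], bad[2]))
  }
  dalpha <- d^alpha
  if (!is.null(depth)) {
    stopifnot(depth >= 0)
    beta <- if (depth == 0) 0 else depth / sum(dalpha[ut])
  }
  stopifnot(beta >= 0)
  set.seed(seed)
  m <- matrix(0, n, n)
  m[ut] <- stats::rpois(sum(ut), beta * dalpha[ut])
  m <- m + t(m)
  bt <- make_bin_table(stats::setNames(n * resolution, chrom), resolution)
  out <- contact_map(m, bt, haplotype = "pooled")
  attr(out, "beta") <- beta
  out
}

.allele_codes <- c(maternal = "M", paternal = "P", none = ".", conflict = "X")

#' Simulate pair records from a diploid pair of contact maps
#'
#' Every contact of each haplotype map emits one pair record with positions
#' drawn uniformly within its bins. Each end independently carries the
#' emitting haplotype's SNP code with probability `snp_informative_rate`
#' (else no evidence); a small fraction of pairs carry a conflicting-SNP
#' code on one end. MAPQ values are drawn per end from a two-point
#' distribution (60 with probability 0.95, else 10) so the MAPQ filter is
#' exercised. Duplicated records (both end coordinates copied exactly) are
#' appended at `dup_rate`.
#'
#' @param maps named list with `maternal` and `paternal` `contact_map`s
#'   sharing a bin table.
#' @param snp_informative_rate per-end probability of a diagnostic SNP.
#' @param dup_rate probability that a pair is duplicated.
#' @param conflict_rate probability that one end carries conflicting
#'   evidence.
#' @param seed integer RNG seed.
#' @return data.frame of pair records: `read_id`, `chrom1`, `pos1`,
#'   `strand1`, `chrom2`, `pos2`, `strand2`, `mapq1`, `mapq2`, `allele1`,
#'   `allele2`, plus the ground-truth `true_hap` column (not written by
#'   [write_pairs()]).
#' @export
simulate_pairs <- function(maps, snp_informative_rate = 0.3, dup_rate = 0.05,
                           conflict_rate = 0.005, seed = 1L) {
  stopifnot(is.list(maps), all(c("maternal", "paternal") %in% names(maps)))
  if (snp_informative_rate < 0 || snp_informative_rate > 1 ||
      dup_rate < 0 || dup_rate >= 1 || conflict_rate < 0 || conflict_rate > 1)
    stop("rates must lie in [0, 1] (dup_rate < 1)")
  bt <- maps$maternal$bins
  if (!identical(dim(maps$maternal$counts), dim(maps$paternal$counts)))
    stop("maps must share a bin table")
  set.seed(seed)
  emit_hap <- function(map, hap) {
    m <- map$counts
    ut <- upper.tri(m, diag = TRUE)
    idx <- which(ut & m > 0, arr.ind = TRUE)
    if (nrow(idx) == 0)
      return(NULL)
    i <- rep(idx[, 1], m[idx]); j <- rep(idx[, 2], m[idx])
    np <- length(i)
    u1 <- stats::runif(np); u2 <- stats::runif(np)
    pos1 <- floor(bt$start[i] + u1 * (bt$end[i] - bt$start[i]))
    pos2 <- floor(bt$start[j] + u2 * (bt$end[j] - bt$start[j]))
    code <- .allele_codes[[hap]]
    a1 <- ifelse(stats::runif(np) < snp_informative_rate, code, ".")
    a2 <- ifelse(stats::runif(np) < snp_informative_rate, code, ".")
    confl <- stats::runif(np) < conflict_rate
    side <- stats::runif(np) < 0.5
    a1[confl & side] <- "X"
    a2[confl & !side] <- "X"
    data.frame(chrom1 = bt$chrom[i], pos1 = pos1,
               strand1 = sample(c("+", "-"), np, replace = TRUE),
               chrom2 = bt$chrom[j], pos2 = pos2,
               strand2 = sample(c("+", "-"), np, replace = TRUE),
               mapq1 = sample(c(60L, 10L), np, replace = TRUE,
                              prob = c(0.95, 0.05)),
               mapq2 = sample(c(60L, 10L), np, replace = TRUE,
                              prob = c(0.95, 0.05)),
               allele1 = a1, allele2 = a2, true_hap = hap,
               stringsAsFactors = FALSE)
  }
  pairs <- rbind(emit_hap(maps$maternal, "maternal"),
                 emit_hap(maps$paternal, "paternal"))
  if (is.null(pairs) || nrow(pairs) == 0) {
    pairs <- data.frame(chrom1 = character(), pos1 = numeric(),
                        strand1 = character(), chrom2 = character(),
                        pos2 = numeric(), strand2 = character(),
                        mapq1 = integer(), mapq2 = integer(),
                        allele1 = character(), allele2 = character(),
                        true_hap = character(), stringsAsFactors = FALSE)
  }
  if (nrow(pairs) > 0) {
    pairs$read_id <- sprintf("read%07d", seq_len(nrow(pairs)))
    dup <- which(stats::runif(nrow(pairs)) < dup_rate)
    if (length(dup) > 0) {
      dups <- pairs[dup, ]
      dups$read_id <- sprintf("dup%07d", seq_along(dup))
      pairs <- rbind(pairs, dups)
    }
  } else {
    pairs$read_id <- character()
  }
  rownames(pairs) <- NULL
  pairs[, c("read_id", "chrom1", "pos1", "strand1", "chrom2", "pos2",
            "strand2", "mapq1", "mapq2", "allele1", "allele2", "true_hap")]
}

#' Plant a 1D feature track with radial bias
#'
#' Distributes `n_peaks` feature peaks over bins with sampling weight
#' `exp(peripheral_bias * u_i)` where `u_i` is the radial distance of
#' bead `i` (to the origin, or to the nearest of the supplied centers)
#' rescaled to [0, 1], so `peripheral_bias` is the log weight ratio
#' between the most peripheral and the most interior bin.
#' `peripheral_bias = 0` gives exchangeable bins.
#'
#' @param struct a `structure3d`.
#' @param n_peaks total number of peaks to distribute.
#' @param peripheral_bias non-negative bias strength.
#' @param seed integer RNG seed.
#' @param centers optional matrix of center coordinates (rows); default is
#'   the origin.
#' @return data.frame with columns `bin`, `density`.
#' @export
plant_features <- function(struct, n_peaks, peripheral_bias = 0, seed = 1L,
                           centers = NULL) {
  stopifnot(inherits(struct, "structure3d"), peripheral_bias >= 0,
            n_peaks >= 0)
  n <- nrow(struct$coords)
  if (is.null(centers)) centers <- matrix(0, 1, 3)
  r <- apply(struct$coords, 1, function(x)
    min(sqrt(colSums((t(centers) - x)^2))))
  u <- if (diff(range(r)) > 0) (r - min(r)) / diff(range(r)) else rep(0, n)
  set.seed(seed)
  dens <- if (n_peaks == 0) rep(0L, n) else
    as.integer(stats::rmultinom(1, n_peaks, exp(peripheral_bias * u)))
  data.frame(bin = seq_len(n), density = dens)
}

#' Build a synthetic gene table with planted allelic effects
#'
#' Places genes in distinct bins and draws allelic RNA read counts from a
#' binomial whose maternal proportion is `m / (m + 1)` for a planted
#' expressed-allele multiplier `m` (1 for unbiased background genes).
#' Imprinted and escape specs give, per category, the number of genes, the
#' RNA multiplier toward the expressed allele, and a planted allelic
#' contact multiplier recorded for recovery oracles. Escape genes also get
#' PolII SNP read counts in ten 100-bp intervals around the TSS.
#'
#' @param bin_table bin table from [make_bin_table()].
#' @param n_genes total genes; must not exceed the number of bins.
#' @param imprinted_spec list with `n_maternal`, `n_paternal`,
#'   `rna_multiplier`, `contact_multiplier`.
#' @param escape_spec list with `n`, `contact_multiplier`, `polii_mean`.
#' @param n_reads RNA reads per gene.
#' @param seed integer RNG seed.
#' @return data.frame (one row per gene) with columns `id`, `chrom`,
#'   `start`, `end`, `strand`, `category`, `rna_maternal`, `rna_paternal`,
#'   `contact_multiplier`, and a `polii` matrix column; ground truth is in
#'   attribute `ground_truth`.
#' @export
make_gene_table <- function(bin_table, n_genes,
                            imprinted_spec = list(n_maternal = 0,
                                                  n_paternal = 0,
                                                  rna_multiplier = 10,
                                                  contact_multiplier = 3),
                            escape_spec = list(n = 0,
                                               contact_multiplier = 2,
                                               polii_mean = 10),
                            n_reads = 100, seed = 1L) {
  n_bins <- nrow(bin_table)
  if (n_genes > n_bins) stop("more genes than bins")
  if (n_genes == 0)
    return(data.frame(id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), category = character(),
                      rna_maternal = integer(), rna_paternal = integer(),
                      contact_multiplier = numeric(),
                      stringsAsFactors = FALSE))
  set.seed(seed)
  n_im <- imprinted_spec$n_maternal %||% 0
  n_ip <- imprinted_spec$n_paternal %||% 0
  n_esc <- escape_spec$n %||% 0
  if (n_im + n_ip + n_esc > n_genes)
    stop("category counts exceed n_genes")
  # escape genes live on chrX when present in the bin table
  xbins <- bin_table$bin[bin_table$chrom == "chrX"]
  abins <- bin_table$bin[bin_table$chrom != "chrX"]
  if (n_esc > 0 && length(xbins) == 0)
    stop("escape genes require chrX bins")
  pick <- function(pool, k) if (k > 0) sample(pool, k) else integer(0)
  esc_bins <- pick(xbins, min(n_esc, length(xbins)))
  rest_pool <- setdiff(bin_table$bin, esc_bins)
  other_bins <- pick(rest_pool, n_genes - length(esc_bins))
  bins <- c(esc_bins, other_bins)
  category <- c(rep("escape", length(esc_bins)),
                rep("imprinted-maternal", n_im),
                rep("imprinted-paternal", n_ip),
                rep(NA_character_, n_genes - n_esc - n_im - n_ip))
  chrom <- bin_table$chrom[bins]
  category[is.na(category)] <- ifelse(chrom[is.na(category)] == "chrX",
                                      "background-X", "background-autosomal")
  res <- attr(bin_table, "resolution")
  glen <- max(200, floor(res / 10))
  start <- bin_table$start[bins] + floor(res / 4)
  end <- pmin(start + glen, bin_table$end[bins])
  rna_mult <- ifelse(category == "imprinted-maternal",
                     imprinted_spec$rna_multiplier,
              ifelse(category == "imprinted-paternal",
                     1 / imprinted_spec$rna_multiplier, 1))
  p_mat <- rna_mult / (1 + rna_mult)
  rna_m <- stats::rbinom(n_genes, n_reads, p_mat)
  contact_mult <- ifelse(category == "imprinted-maternal",
                         imprinted_spec$contact_multiplier,
                  ifelse(category == "imprinted-paternal",
                         1 / imprinted_spec$contact_multiplier,
                  ifelse(category == "escape",
                         escape_spec$contact_multiplier, 1)))
  genes <- data.frame(id = sprintf("gene%04d", seq_len(n_genes)),
                      chrom = chrom, start = start, end = end,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      category = category, rna_maternal = rna_m,
                      rna_paternal = n_reads - rna_m,
                      contact_multiplier = contact_mult,
                      stringsAsFactors = FALSE)
  polii <- matrix(stats::rpois(n_genes * 10,
                               ifelse(category == "escape",
                                      escape_spec$polii_mean %||% 10, 1)),
                  n_genes, 10)
  genes$polii <- polii
  attr(genes, "ground_truth") <- data.frame(id = genes$id,
                                            contact_multiplier = contact_mult)
  genes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plant an allelic contact bias at gene bins
#'
#' Scales every contact with at least one anchor in a gene's bins by that
#' gene's planted multiplier (symmetrically), then redraws Poisson counts.
#' Used to create maps in which the expressed allele has `m`-fold more
#' contacts at the gene, so the virtual-4C log-ratio converges to
#' `log10(m)`.
#'
#' @param map a `contact_map` (expected counts are taken from it).
#' @param genes gene table rows to bias.
#' @param multipliers per-gene multipliers (same length as `genes` rows).
#' @param seed integer RNG seed.
#' @return a new `contact_map` with redrawn counts.
#' @export
plant_contact_bias <- function(map, genes, multipliers, seed = 1L) {
  stopifnot(nrow(genes) == length(multipliers))
  lam <- map$counts
  for (g in seq_len(nrow(genes))) {
    bins <- gene_bins(genes[g, ], map$bins)
    touched <- outer(seq_len(nrow(lam)) %in% bins,
                     seq_len(nrow(lam)) %in% bins, "|")
    lam[touched] <- lam[touched] * multipliers[g]
  }
  set.seed(seed)
  ut <- upper.tri(lam, diag = TRUE)
  m <- matrix(0, nrow(lam), ncol(lam))
  m[ut] <- stats::rpois(sum(ut), lam[ut])
  m <- m + t(m) - diag(diag(m))
  out <- map
  out$counts <- m
  out
}

# bins (global indices) overlapped by a gene body [start, end)
gene_bins <- function(gene, bin_table) {
  with(bin_table,
       bin[chrom == gene$chrom & start < gene$end & end > gene$start])
}
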