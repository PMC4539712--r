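#' Build a genome bin table
#'
#' Partitions each chromosome into non-overlapping, fixed-width bins
#' (0-based, half-open coordinates). The final bin of a chromosome may be
#' shorter than `resolution`. Within a chromosome the bin holding position
#' `pos` is `floor(pos / resolution)`; the `bin` column is the global
#' 1-based row index used by all matrices in the package.
#'
#' @param chrom_sizes named integer vector of chromosome lengths in bp.
#' @param resolution bin width in bp (e.g. 1e6, 1e5, 4e4).
#' @return data.frame with columns `chrom`, `start`, `end`, `bin`.
#' @examples
#' bt <- make_bin_table(c(chrX = 166650296), 1e6)
#' nrow(bt)  # 167
#' @export
make_bin_table <- function(chrom_sizes, resolution) {
  stopifnot(length(chrom_sizes) >= 1, resolution > 0)
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  tabs <- lapply(names(chrom_sizes), function(ch) {
    len <- as.numeric(chrom_sizes[[ch]])
    n <- ceiling(len / resolution)
    start <- (seq_len(n) - 1) * resolution
    data.frame(chrom = ch, start = start,
               end = pmin(start + resolution, len),
               stringsAsFactors = FALSE)
  })
  bt <- do.call(rbind, tabs)
  bt$bin <- seq_len(nrow(bt))
  attr(bt, "resolution") <- resolution
  bt
}

#' Allelic contact map container
#'
#' A symmetric, non-negative contact count matrix over the bins of a
#' [make_bin_table()] bin table, together with a haplotype label and a
#' per-bin validity mask. Masked bins have all-zero rows/columns after
#' preprocessing.
#'
#' @param counts symmetric non-negative numeric matrix, one row per bin.
#' @param bins bin table from [make_bin_table()].
#' @param haplotype one of `"maternal"`, `"paternal"`, `"pooled"`,
#'   `"inferred-maternal"`, `"inferred-paternal"`.
#' @param mask logical vector, `TRUE` for valid bins.
#' @return object of class `contact_map`.
#' @export
contact_map <- function(counts, bins,
                        haplotype = c("pooled", "maternal", "paternal",
                                      "inferred-maternal",
                                      "inferred-paternal"),
                        mask = NULL) {
  haplotype <- match.arg(haplotype)
  counts <- as.matrix(counts)
  n <- nrow(bins)
  if (!all(dim(counts) == c(n, n)))
    stop("counts must be ", n, "x", n, " to match the bin table")
  if (any(counts < 0)) stop("contact counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-8) stop("counts must be symmetric")
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n)
  structure(list(counts = counts, bins = bins, haplotype = haplotype,
                 mask = mask, resolution = attr(bins, "resolution"),
                 balanced = FALSE),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map [%s]: %d bins (%d masked), %s contacts, %s\n",
              x$haplotype, nrow(x$counts), sum(!x$mask),
              format(round(map_total(x), 2)),
              if (x$balanced) "balanced" else "raw counts"))
  invisible(x)
}

#' Total contacts in a map (upper triangle plus diagonal)
#' @param map a `contact_map`.
#' @return numeric scalar.
#' @export
map_total <- function(map) {
  m <- map$counts
  sum(m[upper.tri(m, diag = TRUE)])
}

#' Map genomic positions to global bin indices
#'
#' Within a chromosome the bin is `floor(pos / resolution)`; the returned
#' index is the global 1-based row of the bin table.
#'
#' @param chrom,pos parallel vectors of chromosome names and 0-based
#'   positions.
#' @param bin_table bin table from [make_bin_table()].
#' @return integer vector of global bin indices.
#' @export
pos_to_bin <- function(chrom, pos, bin_table) {
  res <- attr(bin_table, "resolution")
  chroms <- unique(bin_table$chrom)
  offs <- vapply(chroms, function(ch) min(bin_table$bin[bin_table$chrom == ch]),
                 numeric(1)) - 1
  nbin <- vapply(chroms, function(ch) sum(bin_table$chrom == ch), numeric(1))
  ci <- match(chrom, chroms)
  if (anyNA(ci)) stop("chromosome not in bin table: ",
                      paste(unique(chrom[is.na(ci)]), collapse = ", "))
  within <- floor(pos / res)
  bad <- within >= nbin[ci] | pos < 0
  if (any(bad))
    stop("position beyond chromosome end in record(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  as.integer(offs[ci] + within + 1)
}

#' Bin classified contact pairs into allelic contact maps
#'
#' Each pair increments `C[i, j]` and `C[j, i]` by 1 (diagonal pairs
#' increment `C[i, i]` once). Maternal and paternal pairs go to their
#' haplotype map; allele-uncertain pairs go to a pooled-coordinate map that
#' feeds the EM stage. `inter_homolog` and `discard` categories are
#' tabulated but excluded from the maps.
#'
#' @param pairs data.frame of pair records with a `category` column (see
#'   [classify_pairs()]).
#' @param bin_table bin table from [make_bin_table()].
#' @return named list of `contact_map`s: `maternal`, `paternal`,
#'   `uncertain`, plus a `category_counts` table.
#' @export
bin_pairs <- function(pairs, bin_table) {
  if (is.null(pairs$category)) stop("pairs must carry a 'category' column")
  n <- nrow(bin_table)
  one_map <- function(sub, label) {
    m <- matrix(0, n, n)
    if (nrow(sub) > 0) {
      i <- pos_to_bin(sub$chrom1, sub$pos1, bin_table)
      j <- pos_to_bin(sub$chrom2, sub$pos2, bin_table)
      lo <- pmin(i, j); hi <- pmax(i, j)
      tab <- table(factor(paste(lo, hi), levels = unique(paste(lo, hi))))
      key <- do.call(rbind, strsplit(names(tab), " "))
      ii <- as.integer(key[, 1]); jj <- as.integer(key[, 2])
      m[cbind(ii, jj)] <- as.numeric(tab)
      m[cbind(jj, ii)] <- m[cbind(ii, jj)]
    }
    contact_map(m, bin_table, haplotype = label)
  }
  out <- list(
    maternal  = one_map(pairs[pairs$category == "maternal", ], "maternal"),
    paternal  = one_map(pairs[pairs$category == "paternal", ], "paternal"),
    uncertain = one_map(pairs[pairs$category == "uncertain", ], "pooled"))
  out$category_counts <- table(factor(pairs$category,
    levels = c("maternal", "paternal", "uncertain",
               "inter_homolog", "discard")))
  out
}

#' Preprocess a contact map before balancing
#'
#' Zeroes the diagonal and the +/-1 off-diagonals within each chromosome
#' (entries dominated by self-ligation products), then masks low-coverage
#' bins: per chromosome, the `floor(coverage_quantile * n_bins)` bins with
#' the lowest row-sum coverage (computed before zeroing; ties broken by
#' lower bin index), plus any bins left with no contacts after zeroing.
#' Masked rows and columns are set to zero. The operation is idempotent.
#'
#' @param map a `contact_map`.
#' @param coverage_quantile fraction of lowest-coverage bins to exclude
#'   per chromosome (default 0.02).
#' @return preprocessed `contact_map` with updated mask.
#' @export
preprocess_map <- function(map, coverage_quantile = 0.02) {
  stopifnot(inherits(map, "contact_map"),
            coverage_quantile >= 0, coverage_quantile < 1)
  m <- map$counts
  n <- nrow(m)
  coverage <- rowSums(m)                    # before zeroing, incl. diagonal
  # zero |i - j| <= 1 within each chromosome (trans entries untouched)
  for (ch in unique(map$bins$chrom)) {
    idx <- map$bins$bin[map$bins$chrom == ch]
    for (k in idx) {
      for (l in intersect(c(k - 1, k, k + 1), idx)) m[k, l] <- 0
    }
  }
  mask <- map$mask
  for (ch in unique(map$bins$chrom)) {
    idx <- map$bins$bin[map$bins$chrom == ch]
    k <- floor(coverage_quantile * length(idx))
    if (k > 0) {
      low <- idx[order(coverage[idx], idx)][seq_len(k)]
      mask[low] <- FALSE
    }
  }
  mask[rowSums(m) == 0] <- FALSE
  if (!any(mask))
    warning("all bins masked during preprocessing; map is all zero")
  m[!mask, ] <- 0
  m[, !mask] <- 0
  out <- map
  out$counts <- m
  out$mask <- mask
  out
}

#' Iterative correction (matrix balancing)
#'
#' Removes multiplicative per-bin biases from a preprocessed map by
#' iteratively dividing rows and columns by their marginal relative to the
#' mean unmasked marginal, until row sums are near-equal. Each chromosome's
#' cis block is balanced separately; trans entries are zeroed (only
#' intrachromosomal contacts are used for normalization). The output is
#' scaled to unit mean row sum over unmasked bins.
#'
#' @param map preprocessed `contact_map`.
#' @param tol convergence tolerance on the maximum relative deviation of
#'   unmasked row sums (default 1e-4).
#' @param max_iter maximum iterations (default 1000; nearly
#'   block-decomposable maps, e.g. strongly bipartite chromosomes,
#'   converge slowly).
#' @return balanced `contact_map` with attributes `converged` and
#'   `iterations`.
#' @export
ice_normalize <- function(map, tol = 1e-4, max_iter = 1000) {
  stopifnot(inherits(map, "contact_map"))
  m <- map$counts
  # drop trans entries
  chrom_of <- map$bins$chrom
  trans <- outer(chrom_of, chrom_of, "!=")
  m[trans] <- 0
  converged <- TRUE
  iters <- integer(0)
  for (ch in unique(chrom_of)) {
    idx <- which(chrom_of == ch & map$mask)
    if (length(idx) < 2) next
    b <- m[idx, idx, drop = FALSE]
    it <- 0; ok <- FALSE
    while (it < max_iter) {
      it <- it + 1
      s <- rowSums(b)
      if (all(s == 0)) break
      rel <- s / mean(s)
      b <- b / outer(rel, rel)
      if (max(abs(rowSums(b) / mean(rowSums(b)) - 1)) < tol) { ok <- TRUE; break }
    }
    if (!ok) {
      warning("iterative correction did not converge for ", ch,
              " in ", max_iter, " iterations")
      converged <- FALSE
    }
    s <- rowSums(b)
    if (mean(s) > 0) b <- b / mean(s)       # unit mean row sum
    m[idx, idx] <- b
    iters <- c(iters, it)
  }
  out <- map
  out$counts <- m
  out$balanced <- TRUE
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iters
  out
}
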