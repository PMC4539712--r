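# Gene-centric allelic contact analysis: imprinted/escape/background
# gene selection, virtual-4C maternal-to-paternal contact log-ratios,
# and distribution comparisons.

#' Select imprinted genes with confirmed allelic expression bias
#'
#' The background binomial proportion is `p0 = r / (1 + r)` where `r` is
#' the mean maternal-to-paternal RNA count ratio over autosomal
#' background genes with paternal count > 0 (capturing e.g. reference
#' mapping bias). Each candidate gets a one-sided exact binomial test of
#' its maternal count out of the total, toward its putatively expressed
#' allele; Benjamini-Hochberg correction is applied across candidates
#' and genes with `q < q_threshold` are retained.
#'
#' @param genes gene table with `category`, `rna_maternal`,
#'   `rna_paternal` (categories `imprinted-maternal` /
#'   `imprinted-paternal` are the candidates; `background-autosomal`
#'   genes form the background).
#' @param q_threshold BH-adjusted significance cutoff (default 0.05).
#' @return the retained candidate rows with added `p_value` and `q_value`
#'   columns; attribute `p0` records the background proportion.
#' @export
select_imprinted <- function(genes, q_threshold = 0.05) {
  bg <- genes[genes$category == "background-autosomal" &
                genes$rna_paternal > 0, ]
  if (nrow(bg) == 0) stop("empty autosomal background")
  r <- mean(bg$rna_maternal / bg$rna_paternal)
  p0 <- r / (1 + r)
  cand <- genes[genes$category %in% c("imprinted-maternal",
                                      "imprinted-paternal"), ]
  if (nrow(cand) == 0) {
    out <- cand
    out$p_value <- numeric(0); out$q_value <- numeric(0)
    attr(out, "p0") <- p0
    return(out)
  }
  pv <- vapply(seq_len(nrow(cand)), function(g) {
    tot <- cand$rna_maternal[g] + cand$rna_paternal[g]
    if (tot == 0) return(1)
    alt <- if (cand$category[g] == "imprinted-maternal") "greater" else "less"
    stats::binom.test(cand$rna_maternal[g], tot, p = p0,
                      alternative = alt)$p.value
  }, numeric(1))
  cand$p_value <- pv
  cand$q_value <- stats::p.adjust(pv, method = "BH")
  out <- cand[cand$q_value < q_threshold, ]
  attr(out, "p0") <- p0
  out
}

#' Select escape genes by promoter PolII occupancy
#'
#' Retains genes whose mean PolII SNP read count over the ten 100-bp
#' intervals spanning TSS +/- 0.5 kb is at least `polii_min`
#' (boundary inclusive). Genes with missing interval counts are skipped
#' with a warning.
#'
#' @param genes gene table with a `polii` matrix column (10 intervals).
#' @param polii_min minimum mean count (default 5).
#' @return the retained rows.
#' @export
select_escape <- function(genes, polii_min = 5) {
  if (is.null(genes$polii)) stop("gene table lacks PolII interval counts")
  missing <- apply(genes$polii, 1, function(x) any(is.na(x)))
  if (any(missing))
    warning(sum(missing), " gene(s) skipped: missing PolII intervals")
  means <- rowMeans(genes$polii)
  genes[!missing & means >= polii_min, , drop = FALSE]
}

#' Build the background gene set for contact-ratio comparisons
#'
#' Removes genes sharing a Hi-C window (bin) with any focal gene,
#' collapses multiple remaining genes in one window to a single gene
#' (the lowest start coordinate), and drops genes with no contacts in
#' the pooled map. The result is split into autosomal and X-linked
#' backgrounds.
#'
#' @param genes full gene table.
#' @param focal_ids ids of focal (imprinted or escape) genes.
#' @param pooled_map `contact_map` of pooled (bulk) contacts.
#' @return list with `autosomal` and `x_linked` gene tables.
#' @export
build_background <- function(genes, focal_ids, pooled_map) {
  bt <- pooled_map$bins
  win <- lapply(seq_len(nrow(genes)), function(g) gene_bins(genes[g, ], bt))
  focal <- genes$id %in% focal_ids
  focal_windows <- unique(unlist(win[focal]))
  keep <- !focal & !vapply(win, function(w) any(w %in% focal_windows),
                           logical(1))
  cand <- genes[keep, , drop = FALSE]
  cwin <- vapply(win[keep], function(w) w[1], integer(1))
  # one gene per window: lowest start coordinate
  ord <- order(cwin, cand$start)
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[!duplicated(cwin[ord]), , drop = FALSE]
  colsum <- rowSums(pooled_map$counts)
  has_contact <- vapply(seq_len(nrow(cand)), function(g)
    sum(colsum[gene_bins(cand[g, ], bt)]) > 0, logical(1))
  cand <- cand[has_contact, , drop = FALSE]
  list(autosomal = cand[cand$chrom != "chrX", , drop = FALSE],
       x_linked = cand[cand$chrom == "chrX", , drop = FALSE])
}

#' Virtual-4C allelic contact ratio for genes
#'
#' For each gene, sums all entries of the maternal and paternal map
#' columns whose bins overlap the gene body (masked rows excluded) and
#' returns the pseudocounted log-ratio
#' `log10((maternal + 1) / (paternal + 1))`.
#'
#' @param maternal_map,paternal_map allelic `contact_map`s at the
#'   analysis resolution.
#' @param genes gene table rows overlapping the maps' coordinates.
#' @return data.frame with `id`, `maternal`, `paternal`, `log_ratio`.
#' @export
virtual4c_ratio <- function(maternal_map, paternal_map, genes) {
  bt <- maternal_map$bins
  okm <- maternal_map$mask; okp <- paternal_map$mask
  res <- lapply(seq_len(nrow(genes)), function(g) {
    bins <- gene_bins(genes[g, ], bt)
    if (length(bins) == 0)
      stop("gene ", genes$id[g], " lies outside the contact map")
    m <- sum(maternal_map$counts[okm, bins, drop = FALSE])
    p <- sum(paternal_map$counts[okp, bins, drop = FALSE])
    c(m, p)
  })
  m <- vapply(res, `[`, numeric(1), 1)
  p <- vapply(res, `[`, numeric(1), 2)
  # difference of logs keeps map-swap antisymmetry exact in floating point
  data.frame(id = genes$id, maternal = m, paternal = p,
             log_ratio = log10(m + 1) - log10(p + 1),
             stringsAsFactors = FALSE)
}

#' Compare allelic log-ratio distributions
#'
#' Two-sided Kolmogorov-Smirnov test of the focal set against the
#' background distribution, with the Wilcoxon rank-sum p value and the
#' median shift reported as cross-checks.
#'
#' @param focal,background numeric vectors of log-ratios.
#' @return list with `ks_statistic`, `ks_p`, `wilcox_p`, `median_shift`,
#'   and an `unreliable` flag when either set has fewer than 3 values.
#' @export
compare_ratio_distributions <- function(focal, background) {
  if (length(focal) == 0 || length(background) == 0)
    stop("both ratio sets must be non-empty")
  ks <- suppressWarnings(stats::ks.test(focal, background))
  wl <- suppressWarnings(stats::wilcox.test(focal, background))
  list(ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       wilcox_p = wl$p.value,
       median_shift = stats::median(focal) - stats::median(background),
       unreliable = length(focal) < 3 || length(background) < 3)
}
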