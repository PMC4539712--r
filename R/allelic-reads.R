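# Haplotype segregation of pair records: MAPQ filtering, PCR-duplicate
# removal, and classification by per-end SNP evidence.

#' Filter pair records on mapping quality
#'
#' Retains a record iff both ends have MAPQ at or above the threshold
#' (default 30, the usual cutoff for high-quality uniquely mapped reads).
#'
#' @param pairs data.frame of pair records with `mapq1`, `mapq2`.
#' @param mapq_min minimum MAPQ (default 30).
#' @return filtered data.frame.
#' @export
filter_pairs <- function(pairs, mapq_min = 30) {
  stopifnot(mapq_min >= 0)
  pairs[pairs$mapq1 >= mapq_min & pairs$mapq2 >= mapq_min, , drop = FALSE]
}

#' Remove redundant (PCR-duplicate) pair records
#'
#' Two records are redundant when both ends map to identical locations,
#' in either end order. Among each redundant set exactly one record (the
#' first in input order) is retained; survivor order is stable.
#'
#' @param pairs data.frame of pair records.
#' @return deduplicated data.frame.
#' @export
deduplicate <- function(pairs) {
  if (nrow(pairs) == 0) return(pairs)
  e1 <- paste(pairs$chrom1, pairs$pos1, sep = ":")
  e2 <- paste(pairs$chrom2, pairs$pos2, sep = ":")
  key <- ifelse(e1 <= e2, paste(e1, e2), paste(e2, e1))
  pairs[!duplicated(key), , drop = FALSE]
}

#' Classify pair records by parental haplotype
#'
#' Evidence codes per end are `M` (maternal SNP), `P` (paternal SNP),
#' `.` (no diagnostic SNP), `X` (conflicting SNPs). A pair with evidence
#' from one parent (on either or both ends) is assigned to that parent;
#' no evidence on either end is `uncertain`; opposite parents on the two
#' ends is `inter_homolog`; any conflicting evidence is `discard`.
#'
#' @param pairs data.frame with `allele1`, `allele2` columns.
#' @return the input with an added `category` factor column with levels
#'   `maternal`, `paternal`, `uncertain`, `inter_homolog`, `discard`.
#' @export
classify_pairs <- function(pairs) {
  a1 <- pairs$allele1; a2 <- pairs$allele2
  known <- c("M", "P", ".", "X")
  bad <- !(a1 %in% known) | !(a2 %in% known)
  if (any(bad))
    stop("unknown allele evidence code in record(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  cat_ <- rep("uncertain", nrow(pairs))
  cat_[(a1 == "M" & a2 %in% c("M", ".")) |
       (a1 == "." & a2 == "M")] <- "maternal"
  cat_[(a1 == "P" & a2 %in% c("P", ".")) |
       (a1 == "." & a2 == "P")] <- "paternal"
  cat_[(a1 == "M" & a2 == "P") | (a1 == "P" & a2 == "M")] <- "inter_homolog"
  cat_[a1 == "X" | a2 == "X"] <- "discard"
  pairs$category <- factor(cat_, levels = c("maternal", "paternal",
                                            "uncertain", "inter_homolog",
                                            "discard"))
  pairs
}

#' Segregate pair records into haplotype categories
#'
#' Convenience wrapper running the standard order: MAPQ filter, global
#' PCR-duplicate removal (so category counts are computed on unique
#' molecules), then classification.
#'
#' @inheritParams filter_pairs
#' @return list with `pairs` (filtered, deduplicated, classified) and
#'   `summary` (category counts plus records removed by each step).
#' @export
segregate_pairs <- function(pairs, mapq_min = 30) {
  n0 <- nrow(pairs)
  flt <- filter_pairs(pairs, mapq_min)
  ddp <- deduplicate(flt)
  cls <- classify_pairs(ddp)
  list(pairs = cls,
       summary = list(input = n0,
                      removed_mapq = n0 - nrow(flt),
                      removed_duplicates = nrow(flt) - nrow(ddp),
                      categories = table(cls$category)))
}
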