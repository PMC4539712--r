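# Plain-text I/O: pairs records, sparse contact matrices with BED bin
# tables, and 3D structures. All formats are tab-separated with "#"
# header lines.

#' Write pair records to a pairs-style text file
#'
#' Columns: readID, chrom1, pos1 (0-based), strand1, chrom2, pos2,
#' strand2, mapq1, mapq2, allele1, allele2 with allele codes in
#' \{M, P, ., X\}. Header lines are prefixed `#`. The ground-truth
#' `true_hap` column, when present, is not written.
#'
#' @param pairs data.frame of pair records.
#' @param path output file path.
#' @export
write_pairs <- function(pairs, path) {
  cols <- c("read_id", "chrom1", "pos1", "strand1", "chrom2", "pos2",
            "strand2", "mapq1", "mapq2", "allele1", "allele2")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("## pairs-like text, tab-separated",
               paste0("#columns: ", paste(cols, collapse = "\t"))), con)
  utils::write.table(pairs[, cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read pair records written by [write_pairs()]
#' @param path input file path.
#' @return data.frame of pair records.
#' @export
read_pairs <- function(path) {
  cols <- c("read_id", "chrom1", "pos1", "strand1", "chrom2", "pos2",
            "strand2", "mapq1", "mapq2", "allele1", "allele2")
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = cols, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric",
                                         "character", "character", "numeric",
                                         "character", "integer", "integer",
                                         "character", "character"))
  df
}

#' Write a contact map as sparse bin-pair triples plus a BED bin table
#'
#' Emits `<prefix>.matrix.tsv` with columns (bin1, bin2, count) for the
#' non-zero upper triangle (including the diagonal), and `<prefix>.bins.bed`
#' with (chrom, start, end, bin, mask).
#'
#' @param map a `contact_map`.
#' @param prefix output path prefix.
#' @export
write_sparse_map <- function(map, prefix) {
  m <- map$counts
  ut <- upper.tri(m, diag = TRUE)
  idx <- which(ut & m != 0, arr.ind = TRUE)
  trip <- data.frame(bin1 = idx[, 1], bin2 = idx[, 2], count = m[idx])
  con <- file(paste0(prefix, ".matrix.tsv"), "w")
  writeLines(sprintf("#haplotype=%s resolution=%s balanced=%s",
                     map$haplotype, format(map$resolution), map$balanced),
             con)
  utils::write.table(trip[order(trip$bin1, trip$bin2), ], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  bed <- cbind(map$bins[, c("chrom", "start", "end", "bin")],
               mask = as.integer(map$mask))
  utils::write.table(bed, paste0(prefix, ".bins.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a contact map written by [write_sparse_map()]
#' @param prefix path prefix used at write time.
#' @return a `contact_map`.
#' @export
read_sparse_map <- function(prefix) {
  hdr <- readLines(paste0(prefix, ".matrix.tsv"), n = 1)
  hap <- sub(".*haplotype=(\\S+).*", "\\1", hdr)
  res <- as.numeric(sub(".*resolution=(\\S+).*", "\\1", hdr))
  bed <- utils::read.table(paste0(prefix, ".bins.bed"), sep = "\t",
                           col.names = c("chrom", "start", "end", "bin",
                                         "mask"),
                           stringsAsFactors = FALSE)
  bt <- bed[, c("chrom", "start", "end", "bin")]
  attr(bt, "resolution") <- res
  trip <- utils::read.table(paste0(prefix, ".matrix.tsv"), sep = "\t",
                            comment.char = "#",
                            col.names = c("bin1", "bin2", "count"))
  n <- nrow(bt)
  m <- matrix(0, n, n)
  m[cbind(trip$bin1, trip$bin2)] <- trip$count
  m[cbind(trip$bin2, trip$bin1)] <- trip$count
  contact_map(m, bt, haplotype = hap, mask = bed$mask == 1)
}

#' Write a 3D structure as 5-column text (bin, x, y, z, valid)
#' @param struct a `structure3d`.
#' @param path output file path.
#' @export
write_structure <- function(struct, path) {
  df <- data.frame(bin = seq_len(nrow(struct$coords)),
                   x = struct$coords[, 1], y = struct$coords[, 2],
                   z = struct$coords[, 3],
                   valid = as.integer(struct$valid))
  con <- file(path, "w")
  writeLines("#bin\tx\ty\tz\tvalid", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a structure written by [write_structure()]
#' @param path input file path.
#' @return a `structure3d`.
#' @export
read_structure <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("bin", "x", "y", "z", "valid"))
  structure(list(coords = unname(as.matrix(df[, c("x", "y", "z")])),
                 valid = df$valid == 1, mode = NULL, hinge_index = NULL),
            class = "structure3d")
}
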