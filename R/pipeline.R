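# End-to-end orchestration: simulate -> segregate -> bin -> preprocess /
# normalize -> EM -> bipartite / structure / spatial / virtual-4C, driven
# by a flat key = value config, with per-stage summaries and seeds
# recorded for reproducibility.

#' mm9 chromosome X length (bp)
#'
#' Length of the mouse chrX in the NCBI build 37 / mm9 assembly; binning
#' it at 1 Mb yields 167 bins.
#' @export
mm9_chrx_length <- 166650296

#' Read a flat key = value pipeline configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are
#' converted to numeric where possible.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- vapply(kv, `[`, character(1), 1)
  out
}

#' Write a pipeline configuration as key = value text
#' @param config named list.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  writeLines(paste(names(config), unlist(config), sep = " = "), path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Study-condition defaults for the synthetic diploid experiment: a
#' bipartite maternal X (the inactive homolog in a Patski-like skewing)
#' and a globular paternal X, distance-decay exponent -3, per-end SNP
#' informative rate 0.3, 5 % PCR duplicates.
#'
#' @param out_dir output directory.
#' @param seed master seed; stage seeds are derived from it.
#' @return named list accepted by [run_pipeline()].
#' @export
default_config <- function(out_dir = tempfile("diphic_run_"), seed = 1L) {
  list(n_bins = 100, resolution = 1e6, hinge_index = 40, alpha = -3,
       depth = 2e5, snp_informative_rate = 0.3, dup_rate = 0.05,
       conflict_rate = 0.005, mapq_min = 30, coverage_quantile = 0.02,
       ice_tol = 1e-4, em = 1, em_tol = 1e-3, em_max_iter = 50,
       n_shifts = 1000, margin = 0.1, n_starts = 3, out_dir = out_dir,
       seed = as.integer(seed))
}

#' Run the full allele-specific Hi-C pipeline on synthetic data
#'
#' Simulates a diploid experiment from the config's planted truth, then
#' runs haplotype segregation, contact-map construction, preprocessing
#' and iterative correction, EM assignment of uncertain pairs (when
#' `em = 1`), bipartite-index boundary detection with significance
#' testing, and 3D structure inference for both homologs. Stage outputs
#' and a machine-readable run report are written under `out_dir`; the
#' config itself is serialized there verbatim.
#'
#' @param config named list (see [default_config()]) or a path to a
#'   key = value file.
#' @return invisible report list with per-stage summaries.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(default_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(cfg, file.path(cfg$out_dir, "config.txt"))
  seed <- as.integer(cfg$seed)
  report <- list(config = cfg, started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  # --- simulate ---------------------------------------------------------
  xi <- make_structure(cfg$n_bins, "bipartite", hinge_index = cfg$hinge_index,
                       seed = seed)
  xa <- make_structure(cfg$n_bins, "globular", seed = seed + 1L)
  map_m <- simulate_contact_map(xi, alpha = cfg$alpha, depth = cfg$depth,
                                seed = seed + 2L, resolution = cfg$resolution)
  map_p <- simulate_contact_map(xa, alpha = cfg$alpha, depth = cfg$depth,
                                seed = seed + 3L, resolution = cfg$resolution)
  map_m$haplotype <- "maternal"; map_p$haplotype <- "paternal"
  pairs <- simulate_pairs(list(maternal = map_m, paternal = map_p),
                          snp_informative_rate = cfg$snp_informative_rate,
                          dup_rate = cfg$dup_rate,
                          conflict_rate = cfg$conflict_rate,
                          seed = seed + 4L)
  write_pairs(pairs, file.path(cfg$out_dir, "pairs.tsv"))
  write_structure(xi, file.path(cfg$out_dir, "true_structure_maternal.tsv"))
  write_structure(xa, file.path(cfg$out_dir, "true_structure_paternal.tsv"))
  report$simulate <- list(n_pairs = nrow(pairs), seed = seed)

  # --- segregate --------------------------------------------------------
  seg <- segregate_pairs(pairs, mapq_min = cfg$mapq_min)
  report$segregate <- seg$summary

  # --- bin --------------------------------------------------------------
  bt <- map_m$bins
  maps <- bin_pairs(seg$pairs, bt)
  report$bin <- list(maternal = map_total(maps$maternal),
                     paternal = map_total(maps$paternal),
                     uncertain = map_total(maps$uncertain))

  # --- EM ---------------------------------------------------------------
  if (cfg$em == 1) {
    em <- em_assign_uncertain(maps[c("maternal", "paternal")],
                              maps$uncertain, tol = cfg$em_tol,
                              max_iter = cfg$em_max_iter)
    inferred <- em[c("maternal", "paternal")]
    report$em <- list(iterations = em$state$iterations,
                      converged = em$state$converged)
  } else {
    warning("EM disabled: downstream stages use certain-read maps only")
    inferred <- maps[c("maternal", "paternal")]
    report$em <- list(skipped = TRUE)
  }
  write_sparse_map(inferred$maternal,
                   file.path(cfg$out_dir, "map_inferred_maternal"))
  write_sparse_map(inferred$paternal,
                   file.path(cfg$out_dir, "map_inferred_paternal"))

  # --- normalize --------------------------------------------------------
  prep_m <- preprocess_map(maps$maternal, cfg$coverage_quantile)
  prep_p <- preprocess_map(maps$paternal, cfg$coverage_quantile)
  norm_m <- ice_normalize(prep_m, tol = cfg$ice_tol)
  norm_p <- ice_normalize(prep_p, tol = cfg$ice_tol)
  write_sparse_map(norm_m, file.path(cfg$out_dir, "map_balanced_maternal"))
  write_sparse_map(norm_p, file.path(cfg$out_dir, "map_balanced_paternal"))
  report$normalize <- list(masked_maternal = sum(!prep_m$mask),
                           masked_paternal = sum(!prep_p$mask),
                           converged = attr(norm_m, "converged") &&
                             attr(norm_p, "converged"))

  # --- bipartite --------------------------------------------------------
  hinge <- find_hinge(maps$maternal, margin = cfg$margin)
  sig <- bipartite_significance(maps$maternal, hinge$h,
                                n_shifts = cfg$n_shifts,
                                margin = cfg$margin, seed = seed + 5L)
  sig_pat <- bipartite_significance(maps$paternal, hinge$h,
                                    n_shifts = cfg$n_shifts,
                                    margin = cfg$margin, seed = seed + 6L)
  report$bipartite <- list(h = hinge$h, bi = sig$bi, p = sig$p_value,
                           p_paternal = sig_pat$p_value)
  bi_tab <- data.frame(haplotype = c("maternal", "paternal"),
                       h = hinge$h,
                       f1 = c(sig$f1, sig_pat$f1),
                       f2 = c(sig$f2, sig_pat$f2),
                       f_inter = c(sig$f_inter, sig_pat$f_inter),
                       bi = c(sig$bi, sig_pat$bi),
                       p = c(sig$p_value, sig_pat$p_value))
  utils::write.table(bi_tab, file.path(cfg$out_dir, "bipartite.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- structure --------------------------------------------------------
  fit_m <- infer_structure(prep_m, alpha = cfg$alpha,
                           n_starts = cfg$n_starts, seed = seed + 7L)
  fit_p <- infer_structure(prep_p, alpha = cfg$alpha,
                           n_starts = cfg$n_starts, seed = seed + 8L)
  write_structure(fit_m, file.path(cfg$out_dir, "structure_maternal.tsv"))
  write_structure(fit_p, file.path(cfg$out_dir, "structure_paternal.tsv"))
  report$structure <- list(
    rmsd_maternal = procrustes_rmsd(xi, fit_m),
    rmsd_paternal = procrustes_rmsd(xa, fit_p),
    rg_maternal = radius_of_gyration(xi),
    loglik_maternal = attr(fit_m, "model")$loglik)

  report$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  rep_lines <- utils::capture.output(utils::str(report, max.level = 2))
  writeLines(rep_lines, file.path(cfg$out_dir, "report.txt"))
  invisible(report)
}
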