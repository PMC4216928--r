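#' Read a tumor allele-count table
#'
#' Tab-delimited input with header columns `chr`, `position`, `refBase`,
#' `refCount`, `nonRefBase`, `nonRefCount` — one row per germline
#' heterozygous SNP with the tumor's reference and non-reference read
#' counts. Records are validated (duplicate positions are an error) and
#' sorted by chromosome (order of first appearance) and position;
#' unsorted input is sorted with a warning.
#'
#' @param path Input file.
#' @return Data frame with `chrom`, `pos`, `ref_base`, `ref_count`,
#'   `nonref_base`, `nonref_count`, `depth` (= ref + nonref).
#' @export
read_allele_counts <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chr", "position", "refBase", "refCount", "nonRefBase",
            "nonRefCount")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("allele-count file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(raw$position) | !is.finite(raw$refCount) |
               !is.finite(raw$nonRefCount) | raw$refCount < 0 |
               raw$nonRefCount < 0)
  if (length(bad))
    stop("malformed allele-count record at line ", bad[1] + 1L,
         call. = FALSE)
  key <- paste(raw$chr, raw$position)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicated position: ", d, call. = FALSE)
  }
  out <- data.frame(chrom = as.character(raw$chr), pos = raw$position,
                    ref_base = raw$refBase, ref_count = raw$refCount,
                    nonref_base = raw$nonRefBase,
                    nonref_count = raw$nonRefCount,
                    depth = raw$refCount + raw$nonRefCount,
                    stringsAsFactors = FALSE)
  ord <- order(factor(out$chrom, levels = unique(out$chrom)), out$pos)
  if (is.unsorted(ord)) {
    warning("allele counts were not position-sorted; sorting",
            call. = FALSE)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write an allele-count table
#'
#' Inverse of [read_allele_counts()] (round-trip identity).
#'
#' @param counts Data frame in [read_allele_counts()] layout.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(counts, path) {
  out <- data.frame(chr = counts$chrom, position = counts$pos,
                    refBase = counts$ref_base %||% "N",
                    refCount = counts$ref_count,
                    nonRefBase = counts$nonref_base %||% "N",
                    nonRefCount = counts$nonref_count %||%
                      (counts$depth - counts$ref_count))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the fitted-parameter checkpoint for a set of runs
#'
#' One row per cluster-number run: Z, normal proportion, ploidy,
#' prevalences, log-posterior, iterations, convergence flag.
#'
#' @param runs List of [em_fit()] results.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_params_tsv <- function(runs, path) {
  rows <- lapply(runs, function(r) {
    data.frame(num_clusters = r$num_clusters, n = r$params$n,
               phi = r$params$phi,
               prevalences = paste(sprintf("%.4f", 1 - r$params$s),
                                   collapse = ","),
               log_posterior = r$log_posterior, iterations = r$iterations,
               converged = r$converged)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full inference pipeline
#'
#' Assembles per-SNP data (minimum tumor depth filter), fits the model
#' once per cluster number in `cluster_range`, selects the optimal run by
#' minimum S_Dbw, and produces per-SNP calls, segments and the genome
#' summary. When `out_dir` is given, writes the per-SNP table, SEG files,
#' the parameter checkpoint and the selection report, stamped with the
#' package version, seed and a configuration hash.
#'
#' @param data Per-SNP data frame (`chrom`, `pos`, `ref_count`, `depth`,
#'   `logratio`), e.g. from [simulate_dataset()] or assembled via
#'   [read_allele_counts()] + [compute_log_ratio()].
#' @param cluster_range Integer vector of cluster numbers to fit
#'   (default 1:4).
#' @param min_depth Minimum tumor depth at a SNP (default 10).
#' @param panel,priors,trans Model configuration.
#' @param max_iter,tol EM controls.
#' @param seed Seed recorded in the outputs (the fit itself is
#'   deterministic).
#' @param out_dir Optional output directory.
#' @param verbose Report progress.
#' @return List of class `cn_pipeline`: `runs`, `selection`, `fit` (the
#'   selected run), `calls`, `segments`, `summary`, `n_filtered`, `seed`.
#' @export
run_pipeline <- function(data, cluster_range = 1:4, min_depth = 10L,
                         panel = build_genotype_panel(),
                         priors = default_priors(),
                         trans = transition_model(),
                         max_iter = 20L, tol = 1e-4, seed = 1L,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(length(cluster_range) >= 1)
  keep <- data$depth >= min_depth & is.finite(data$logratio)
  filtered <- data[keep, , drop = FALSE]
  rownames(filtered) <- NULL
  validate_snp_data(filtered)
  runs <- lapply(sort(unique(as.integer(cluster_range))), function(z) {
    if (verbose) message("fitting ", z, " cluster(s)...")
    em_fit(filtered, num_clusters = z, panel = panel, priors = priors,
           trans = trans, max_iter = max_iter, tol = tol)
  })
  sel <- select_num_clusters(runs, filtered)
  fit <- sel$selected
  calls <- snp_calls(fit, filtered)
  segments <- decode_to_segments(calls)
  res <- structure(list(runs = runs, selection = sel, fit = fit,
                        calls = calls, segments = segments,
                        summary = summarize_genome(segments),
                        n_filtered = sum(!keep), seed = as.integer(seed)),
                   class = "cn_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# Provenance header written at the top of pipeline outputs.
provenance_lines <- function(res) {
  cfg <- utils::capture.output(utils::str(
    list(seed = res$seed, clusters = res$selection$report$num_clusters)))
  tf <- tempfile()
  writeLines(cfg, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  c(paste0("# cloneCN version ",
           as.character(utils::packageVersion("cloneCN"))),
    paste0("# seed ", res$seed, " config ", hash))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_lines(res)
  snp_path <- file.path(out_dir, "snp_calls.tsv")
  writeLines(hdr, snp_path)
  suppressWarnings(utils::write.table(
    res$calls, snp_path, sep = "\t", quote = FALSE, row.names = FALSE,
    append = TRUE))
  write_seg(res$segments, file.path(out_dir, "segments.seg"))
  write_seg(res$segments, file.path(out_dir, "segments_extended.tsv"),
            extended = TRUE)
  write_params_tsv(res$runs, file.path(out_dir, "params.tsv"))
  utils::write.table(res$selection$report,
                     file.path(out_dir, "selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.cn_pipeline <- function(x, ...) {
  cat(sprintf("Pipeline result: %d SNPs (%d filtered), runs Z = {%s}\n",
              nrow(x$calls), x$n_filtered,
              paste(x$selection$report$num_clusters, collapse = ",")))
  cat(sprintf("Selected Z = %d (S_Dbw %.4f)\n", x$fit$num_clusters,
              x$selection$index))
  print(x$fit)
  cat(sprintf("%d segments; altered fraction %.3f\n", nrow(x$segments),
              x$summary$frac_altered))
  invisible(x)
}
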