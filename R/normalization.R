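#' Read a fixed-width WIG track into a binned-track data frame
#'
#' Thin wrapper over `rtracklayer::import(..., format = "wig")`. The track
#' is expected to be fixed-step with 1-kb bins (start coordinates 1-based).
#'
#' @param path WIG file.
#' @return Data frame with columns `chrom`, `start`, `value`.
#' @export
read_wig <- function(path) {
  gr <- rtracklayer::import(path, format = "wig")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             value = gr$score, stringsAsFactors = FALSE)
}

#' Write a binned track as fixed-step WIG
#'
#' @param track Data frame with `chrom`, `start` and the value column.
#' @param path Output path.
#' @param value Name of the value column (default `"value"`).
#' @param width Bin width in bp (default 1000).
#' @return `path`, invisibly.
#' @export
write_wig <- function(track, path, value = "value", width = 1000L) {
  keep <- is.finite(track[[value]])
  gr <- GenomicRanges::GRanges(
    track$chrom[keep],
    IRanges::IRanges(start = track$start[keep], width = width),
    score = track[[value]][keep])
  rtracklayer::export(gr, path, format = "wig")
  invisible(path)
}

#' Assemble a binned read-depth track
#'
#' Combines count, GC-fraction and mappability tracks (matched on
#' chromosome and bin start) into a single data frame used by
#' [loess_correct()].
#'
#' @param counts,gc,mappability Data frames as returned by [read_wig()];
#'   `gc` and `mappability` may be `NULL`.
#' @return Data frame with `chrom`, `start`, `count`, optional `gc`,
#'   `map` columns.
#' @export
binned_track <- function(counts, gc = NULL, mappability = NULL) {
  tr <- data.frame(chrom = counts$chrom, start = counts$start,
                   count = counts$value, stringsAsFactors = FALSE)
  key <- paste(tr$chrom, tr$start)
  if (!is.null(gc)) tr$gc <- gc$value[match(key, paste(gc$chrom, gc$start))]
  if (!is.null(mappability))
    tr$map <- mappability$value[match(key, paste(mappability$chrom,
                                                 mappability$start))]
  tr
}

#' Loess correction of binned read counts against a bias covariate
#'
#' Fits a loess curve of count versus the covariate on filtered bins and
#' divides each count by its fitted value (rescaled by the median usable
#' count, so the count scale is preserved and correction is
#' scale-equivariant). Standard usage applies GC correction first and
#' mappability correction second, to tumor and normal tracks separately.
#'
#' Bins are excluded from both the fit and the corrected output when the
#' covariate is missing, mappability falls below `map_min`, or the raw
#' count lies outside the `quantile_trim` quantiles — routine outlier
#' guarding for the loess fit.
#'
#' @param track Data frame from [binned_track()] (columns `count`, and
#'   `gc`/`map` as needed; a `corrected` column from a previous pass is
#'   corrected in place).
#' @param covariate `"gc"` or `"mappability"`.
#' @param span,degree Loess smoothing parameters (defaults 0.3, 2).
#' @param map_min Mappability threshold for usable bins (default 0.9).
#' @param quantile_trim Count quantiles retained for fitting
#'   (default `c(0.01, 0.99)`).
#' @param min_bins Minimum usable bins; below this the correction is
#'   skipped with a warning and counts pass through (default 500).
#' @return The track with a `corrected` column (`NA` for excluded bins).
#' @export
loess_correct <- function(track, covariate = c("gc", "mappability"),
                          span = 0.3, degree = 2, map_min = 0.9,
                          quantile_trim = c(0.01, 0.99), min_bins = 500L) {
  covariate <- match.arg(covariate)
  xcol <- if (covariate == "gc") "gc" else "map"
  if (is.null(track[[xcol]]))
    stop("track has no '", xcol, "' column", call. = FALSE)
  y <- track$corrected %||% track$count
  x <- track[[xcol]]
  usable <- is.finite(y) & is.finite(x)
  if (!is.null(track$map)) usable <- usable & !is.na(track$map) &
      track$map >= map_min
  if (!is.null(track$gc)) usable <- usable & !is.na(track$gc)
  qs <- stats::quantile(track$count[usable], quantile_trim, na.rm = TRUE)
  usable <- usable & track$count >= qs[1] & track$count <= qs[2]
  if (sum(usable) < min_bins) {
    warning("only ", sum(usable), " usable bins (< ", min_bins,
            "); ", covariate, " correction skipped", call. = FALSE)
    track$corrected <- ifelse(usable, y, NA_real_)
    return(track)
  }
  fit <- stats::loess(y[usable] ~ x[usable], span = span, degree = degree,
                      family = "symmetric",
                      control = stats::loess.control(iterations = 2L,
                                                     surface = "direct"))
  pred <- stats::predict(fit, x[usable])
  corrected <- rep(NA_real_, nrow(track))
  corrected[usable] <- y[usable] / pred * stats::median(y[usable])
  corrected[corrected <= 0] <- NA_real_
  track$corrected <- corrected
  track
}

#' Per-SNP depth log ratios from corrected tumor and normal tracks
#'
#' Maps each SNP to its overlapping 1-kb bin (1-based bins, bin start
#' `floor((pos - 1)/width) * width + 1`) and returns
#' `log2(corrected_tumor / corrected_normal)`. SNPs whose bin is missing
#' or uncorrected in either track are dropped and reported in the
#' `"dropped"` attribute.
#'
#' @param tumor,normal Corrected tracks (from [loess_correct()]).
#' @param snps Data frame with `chrom`, `pos` (sorted within chromosome).
#' @param width Bin width (default 1000).
#' @return `snps` restricted to retained rows with a `logratio` column;
#'   attribute `dropped` holds the discarded rows.
#' @export
compute_log_ratio <- function(tumor, normal, snps, width = 1000L) {
  if (is.null(tumor$corrected) || is.null(normal$corrected))
    stop("tracks must be corrected first (see loess_correct)",
         call. = FALSE)
  bin_start <- (snps$pos - 1L) %/% width * width + 1L
  key <- paste(snps$chrom, bin_start)
  ct <- tumor$corrected[match(key, paste(tumor$chrom, tumor$start))]
  cn <- normal$corrected[match(key, paste(normal$chrom, normal$start))]
  ok <- is.finite(ct) & is.finite(cn) & cn > 0 & ct > 0
  out <- snps[ok, , drop = FALSE]
  out$logratio <- log2(ct[ok] / cn[ok])
  attr(out, "dropped") <- snps[!ok, , drop = FALSE]
  out
}
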