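#' Per-SNP call table from a fitted model
#'
#' Aligns the decoded path with the input data and annotates each SNP
#' with its genotype call, copy number, cluster and prevalences. Outlier
#' SNPs are bridged: an outlier run flanked by the same state inherits
#' it; otherwise the run is attached to the following (or, at chromosome
#' ends, preceding) segment state.
#'
#' @param fit A [em_fit()] result.
#' @param data The per-SNP data frame the fit was run on.
#' @return Data frame: `chrom`, `pos`, `ref_count`, `depth`,
#'   `allelic_ratio`, `logratio`, `label`, `call`, `copy_number`,
#'   `cluster`, `tumor_prevalence`, `sample_prevalence`, `outlier`.
#' @export
snp_calls <- function(fit, data) {
  stopifnot(nrow(data) == nrow(fit$path))
  panel <- fit$panel
  g <- fit$path$genotype
  z <- fit$path$cluster
  out <- fit$path$outlier
  for (idx in chrom_chains(data)) {
    b <- bridge_outliers(g[idx], z[idx], out[idx])
    g[idx] <- b$g; z[idx] <- b$z
  }
  s <- fit$params$s[z]
  data.frame(chrom = data$chrom, pos = data$pos,
             ref_count = data$ref_count, depth = data$depth,
             allelic_ratio = ifelse(data$depth > 0,
                                    data$ref_count / data$depth, NA_real_),
             logratio = data$logratio,
             label = panel$label[g],
             call = panel$call_class[g],
             copy_number = panel$copy_number[g],
             cluster = z,
             tumor_prevalence = 1 - s,
             sample_prevalence = (1 - fit$params$n) * (1 - s),
             outlier = out,
             stringsAsFactors = FALSE)
}

# Replace outlier positions in a (genotype, cluster) path with flanking
# state assignments; isolated runs flanked by one state inherit it, runs
# at a state change attach to the following state.
bridge_outliers <- function(g, z, outlier) {
  if (!any(outlier)) return(list(g = g, z = z))
  if (all(outlier)) stop("all positions decoded as outliers", call. = FALSE)
  n <- length(g)
  idx <- which(!outlier)
  fi <- findInterval(seq_len(n), idx)           # last non-outlier at/before
  prv_i <- ifelse(fi == 0, NA_integer_, idx[pmax(fi, 1L)])
  ridx <- which(!rev(outlier))
  rfi <- findInterval(seq_len(n), ridx)
  nxt_i <- rev(ifelse(rfi == 0, NA_integer_,    # first non-outlier at/after
                      n + 1L - ridx[pmax(rfi, 1L)]))
  fill <- ifelse(is.na(prv_i), nxt_i,
          ifelse(is.na(nxt_i), prv_i,
          ifelse(g[prv_i] == g[nxt_i] & z[prv_i] == z[nxt_i],
                 prv_i, nxt_i)))
  g[outlier] <- g[fill[outlier]]
  z[outlier] <- z[fill[outlier]]
  list(g = g, z = z)
}

#' Collapse per-SNP calls into maximal constant-state segments
#'
#' Maximal runs of constant (call class, copy number, cluster) within a
#' chromosome become segments spanning the first to last SNP position.
#' Outlier bridging has already been applied by [snp_calls()], so the
#' segments partition the retained SNPs exactly.
#'
#' @param calls A [snp_calls()] table (or any data frame with `chrom`,
#'   `pos`, `call`, `copy_number`, `cluster`, `logratio`, `allelic_ratio`,
#'   `tumor_prevalence`, `sample_prevalence`).
#' @return Data frame of segments: `chrom`, `start`, `end`, `n_snps`,
#'   `call`, `copy_number`, `cluster`, `tumor_prevalence`,
#'   `sample_prevalence`, `median_logratio`, `median_ratio`.
#' @export
decode_to_segments <- function(calls) {
  pieces <- lapply(chrom_chains(calls), function(idx) {
    cc <- calls[idx, , drop = FALSE]
    state <- paste(cc$call, cc$copy_number, cc$cluster, sep = "|")
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.frame(chrom = cc$chrom[starts],
               start = cc$pos[starts], end = cc$pos[ends],
               n_snps = r$lengths,
               call = cc$call[starts],
               copy_number = cc$copy_number[starts],
               cluster = cc$cluster[starts],
               tumor_prevalence = cc$tumor_prevalence[starts],
               sample_prevalence = cc$sample_prevalence[starts],
               median_logratio = mapply(function(a, b)
                 stats::median(cc$logratio[a:b]), starts, ends),
               median_ratio = mapply(function(a, b)
                 stats::median(cc$allelic_ratio[a:b], na.rm = TRUE),
                 starts, ends),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Genome-fraction summary of altered SNPs
#'
#' Fraction of SNPs (and of spanned bases) in non-neutral segments, split
#' into clonal (the highest-prevalence cluster) versus subclonal (all
#' other clusters) events. With a single cluster the subclonal fraction
#' is 0 by definition.
#'
#' @param segments A [decode_to_segments()] table.
#' @return One-row data frame: `frac_altered`, `frac_clonal`,
#'   `frac_subclonal` (SNP fractions) and span-based counterparts.
#' @export
summarize_genome <- function(segments) {
  total_snps <- sum(segments$n_snps)
  span <- pmax(segments$end - segments$start + 1, 1)
  altered <- segments$call != "HET"
  clonal <- altered & segments$cluster == 1L
  subclonal <- altered & segments$cluster > 1L
  data.frame(
    frac_altered = sum(segments$n_snps[altered]) / total_snps,
    frac_clonal = sum(segments$n_snps[clonal]) / total_snps,
    frac_subclonal = sum(segments$n_snps[subclonal]) / total_snps,
    span_altered = sum(span[altered]) / sum(span),
    span_clonal = sum(span[clonal]) / sum(span),
    span_subclonal = sum(span[subclonal]) / sum(span))
}

# Collapse a call/copy-number pair into the three scored aberration
# classes. An SNP can qualify for both deletion and LOH (e.g. DLOH).
.LOH_CALLS <- c("DLOH", "NLOH", "ALOH")

class_membership <- function(call, copy_number) {
  cbind(deletion = copy_number < 2,
        gain = copy_number > 2,
        LOH = call %in% .LOH_CALLS)
}

#' Benchmark precision/recall/F-measure against per-SNP truth
#'
#' Scores predicted calls against a truth set at SNP resolution for the
#' three aberration classes — deletion (copy number < 2), gain (copy
#' number > 2) and LOH (any allele-homozygous call) — plus their
#' unweighted average. If the truth carries event identifiers, per-event
#' recall (the fraction of an event's truth SNPs recovered for the
#' event's class) is reported; an event counts as detected when its
#' recall reaches `detect_tpr`.
#'
#' @param predicted Data frame with `chrom`, `pos`, `call`, `copy_number`.
#' @param truth Data frame with `chrom`, `pos`, `call`, `copy_number` and
#'   optionally `event` (NA for background SNPs).
#' @param detect_tpr Per-event detection threshold (default 0.9).
#' @return List with `by_class` (precision/recall/F per class and
#'   `overall` average row), `events` (per-event recall table or NULL)
#'   and `fpr` (fraction of neutral-truth SNPs predicted non-neutral).
#' @export
performance_metrics <- function(predicted, truth, detect_tpr = 0.9) {
  pk <- paste(predicted$chrom, predicted$pos)
  tk <- paste(truth$chrom, truth$pos)
  if (length(pk) != length(tk) || !all(sort(pk) == sort(tk))) {
    diffs <- c(setdiff(pk, tk), setdiff(tk, pk))
    stop("predicted and truth SNP sets differ at ", length(diffs),
         " positions (e.g. ", paste(utils::head(diffs, 3), collapse = "; "),
         ")", call. = FALSE)
  }
  predicted <- predicted[match(tk, pk), , drop = FALSE]
  pm <- class_membership(predicted$call, predicted$copy_number)
  tm <- class_membership(truth$call, truth$copy_number)
  per_class <- lapply(colnames(pm), function(cl) {
    tp <- sum(pm[, cl] & tm[, cl])
    fp <- sum(pm[, cl] & !tm[, cl])
    fn <- sum(!pm[, cl] & tm[, cl])
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    data.frame(class = cl, precision = prec, recall = rec, f_measure = f)
  })
  by_class <- do.call(rbind, per_class)
  overall <- data.frame(class = "overall",
                        precision = mean(by_class$precision, na.rm = TRUE),
                        recall = mean(by_class$recall, na.rm = TRUE),
                        f_measure = mean(by_class$f_measure, na.rm = TRUE))
  by_class <- rbind(by_class, overall)
  events <- NULL
  if (!is.null(truth$event) && any(!is.na(truth$event))) {
    ev <- which(!is.na(truth$event))
    recov <- rowSums(pm[ev, , drop = FALSE] & tm[ev, , drop = FALSE]) > 0
    agg <- stats::aggregate(recov, by = list(event = truth$event[ev]), mean)
    sz <- stats::aggregate(rep(1, length(ev)),
                           by = list(event = truth$event[ev]), sum)
    events <- data.frame(event = agg$event, n_snps = sz$x, recall = agg$x,
                         detected = agg$x >= detect_tpr)
  }
  neutral <- !tm[, "deletion"] & !tm[, "gain"] & !tm[, "LOH"]
  fpr <- if (any(neutral))
    mean(pm[neutral, "deletion"] | pm[neutral, "gain"] | pm[neutral, "LOH"])
  else NA_real_
  list(by_class = by_class, events = events, fpr = fpr)
}

#' Per-event prevalence recovery against a simulated truth set
#'
#' For each truth event, takes the event's SNPs whose predicted call
#' matches the event's aberration class and summarizes their estimated
#' tumor (and sample) cellular prevalence by the median. Events with
#' fewer than `min_frac` of their SNPs recovered yield no estimate
#' (`NA`): an event that was not called carries no prevalence estimate
#' to compare.
#'
#' @param calls A [snp_calls()] table.
#' @param truth A `truth_set` from [simulate_dataset()].
#' @param min_frac Minimum recovered SNP fraction for an estimate
#'   (default 0.1).
#' @return Data frame per event: truth and estimated tumor/sample
#'   prevalences plus the recovered fraction.
#' @export
event_prevalence_recovery <- function(calls, truth, min_frac = 0.1) {
  stopifnot(!is.null(truth$events))
  key <- paste(calls$chrom, calls$pos)
  tkey <- paste(truth$snps$chrom, truth$snps$pos)
  calls <- calls[match(tkey, key), , drop = FALSE]
  pm <- class_membership(calls$call, calls$copy_number)
  ev <- truth$events
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    idx <- which(!is.na(truth$snps$event) & truth$snps$event == ev$event[i])
    tm <- class_membership(ev$call[i], ev$copy_number[i])
    hit <- rowSums(pm[idx, , drop = FALSE] &
                     tm[rep(1, length(idx)), , drop = FALSE]) > 0
    frac <- mean(hit)
    est_t <- est_s <- NA_real_
    if (frac >= min_frac) {
      est_t <- stats::median(calls$tumor_prevalence[idx][hit])
      est_s <- stats::median(calls$sample_prevalence[idx][hit])
    }
    data.frame(event = ev$event[i], n_snps = ev$n_snps[i],
               truth_tumor = ev$tumor_prevalence[i],
               truth_sample = ev$sample_prevalence[i],
               est_tumor = est_t, est_sample = est_s,
               recovered_frac = frac)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write segments in SEG dialect
#'
#' Tab-delimited `sample, chrom, start, end, n_snps, median_logratio`,
#' with an extended variant carrying the genotype and prevalence columns.
#'
#' @param segments A [decode_to_segments()] table.
#' @param path Output file.
#' @param sample Sample identifier for the first column.
#' @param extended Include genotype/cluster/prevalence columns.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path, sample = "sample", extended = FALSE) {
  base <- data.frame(sample = sample, chrom = segments$chrom,
                     start = segments$start, end = segments$end,
                     n_snps = segments$n_snps,
                     median_logratio = round(segments$median_logratio, 4))
  if (extended) {
    base$call <- segments$call
    base$copy_number <- segments$copy_number
    base$cluster <- segments$cluster
    base$tumor_prevalence <- round(segments$tumor_prevalence, 4)
    base$sample_prevalence <- round(segments$sample_prevalence, 4)
  }
  utils::write.table(base, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
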