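#' Symmetric allelic ratio
#'
#' `max(reference reads, variant reads) / depth`; 0.5 at perfect balance,
#' 1 at complete homozygosity. `NA` at zero depth.
#'
#' @param ref_count,depth Reference read count and total depth.
#' @return Numeric vector in \[0.5, 1\].
#' @export
symmetric_ratio <- function(ref_count, depth) {
  ifelse(depth > 0, pmax(ref_count, depth - ref_count) / depth, NA_real_)
}

#' S_Dbw cluster-validity index
#'
#' Scatter-plus-density index of Halkidi & Vazirgiannis on a feature
#' matrix: `Scat`, the mean ratio of within-cluster to overall variance
#' norms, plus `Dens_bw`, the mean relative density at the midpoints
#' between cluster centers. Lower is better. Features are standardized to
#' unit variance first (the two axes used here — depth log ratio and
#' symmetric allelic ratio — have incomparable scales). For a single
#' cluster `Dens_bw` is defined as 0, so the index reduces to `Scat`.
#'
#' @param features Numeric matrix (rows = observations, columns =
#'   features), typically per-SNP (log ratio, symmetric allelic ratio)
#'   restricted to non-neutral decoded SNPs.
#' @param assignments Integer cluster label per row.
#' @return Non-negative scalar; `NA` if no cluster has >= 2 members.
#' @export
sdbw_index <- function(features, assignments) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(assignments))
  keep <- stats::complete.cases(features) & !is.na(assignments)
  features <- features[keep, , drop = FALSE]
  assignments <- assignments[keep]
  if (!nrow(features)) return(NA_real_)
  sds <- apply(features, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  features <- sweep(features, 2, sds, "/")
  labs <- sort(unique(assignments))
  sizes <- table(factor(assignments, levels = labs))
  labs <- labs[sizes >= 2]
  if (!length(labs)) return(NA_real_)
  z <- length(labs)
  total_var <- apply(features, 2, stats::var)
  norm_total <- sqrt(sum(total_var^2))
  clus_var <- lapply(labs, function(l)
    apply(features[assignments == l, , drop = FALSE], 2, stats::var))
  norms <- vapply(clus_var, function(v) sqrt(sum(v^2)), 0)
  scat <- if (norm_total > 0) mean(norms) / norm_total else 0
  if (z == 1L) return(scat)
  centers <- t(vapply(labs, function(l)
    colMeans(features[assignments == l, , drop = FALSE]),
    numeric(ncol(features))))
  stdev <- sqrt(sum(norms)) / z
  dens <- function(points, at) {
    d <- sqrt(rowSums(sweep(points, 2, at)^2))
    sum(d <= stdev)
  }
  dens_bw <- 0
  for (i in seq_len(z - 1)) {
    for (j in (i + 1):z) {
      pts <- features[assignments %in% labs[c(i, j)], , drop = FALSE]
      dmax <- max(dens(pts, centers[i, ]), dens(pts, centers[j, ]))
      dmid <- dens(pts, (centers[i, ] + centers[j, ]) / 2)
      dens_bw <- dens_bw + if (dmax > 0) dmid / dmax else 0
    }
  }
  scat + 2 * dens_bw / (z * (z - 1))
}

#' S_Dbw index of a fitted model
#'
#' Computes the validity index on the fit's decoded output. Only SNPs
#' decoded to a non-neutral, non-outlier genotype contribute (cluster
#' membership is meaningless for diploid-heterozygous loci). Because
#' per-SNP log-ratio and allelic-ratio values of different prevalence
#' levels overlap heavily at typical coverage — it is the segment-level
#' pooling that separates them — the index is evaluated on *segment
#' medians* of the two features, and separately within each genotype
#' call class (deletions versus gains differ far more than prevalence
#' levels do, and would otherwise dominate the scatter). Per class, the
#' standard [sdbw_index()] is computed over that class's segments with
#' the decoded cluster assignments; classes are averaged weighted by
#' their SNP counts. A single-cluster run scores exactly 1 (pure
#' scatter), so a multi-cluster run is preferred precisely when its
#' cluster splits explain within-class structure.
#'
#' @param fit A [em_fit()] result.
#' @param data The per-SNP data the fit was run on.
#' @param min_snps Minimum segment size for a stable median (default 10).
#' @return Scalar index; `NA` if no aberrant SNPs were decoded.
#' @export
sdbw_of_fit <- function(fit, data, min_snps = 10L) {
  calls <- snp_calls(fit, data)
  seg <- decode_to_segments(calls)
  seg <- seg[seg$call != "HET" & seg$n_snps >= min_snps, , drop = FALSE]
  if (!nrow(seg)) return(NA_real_)
  vals <- wts <- numeric(0)
  for (cl in unique(seg$call)) {
    s <- seg[seg$call == cl, , drop = FALSE]
    if (nrow(s) < 2L) next
    sym <- pmax(s$median_ratio, 1 - s$median_ratio)  # fold mirrored alleles
    idx <- sdbw_index(cbind(s$median_logratio, sym), s$cluster)
    if (!is.na(idx)) {
      vals <- c(vals, idx)
      wts <- c(wts, sum(s$n_snps))
    }
  }
  if (!length(vals)) return(NA_real_)
  sum(vals * wts) / sum(wts)
}

#' Select the number of clonal clusters across fitted runs
#'
#' Returns the run with the minimal S_Dbw index; ties (and runs whose
#' index is undefined because no aberrant SNPs were decoded) resolve
#' toward fewer clusters. If every index is undefined the single-cluster
#' (smallest) run is selected by convention.
#'
#' @param runs List of [em_fit()] results (any order).
#' @param data Per-SNP data shared by the runs.
#' @return List with `selected` (the chosen fit), `index` (its S_Dbw) and
#'   `report` (data frame over runs: Z, S_Dbw, log-posterior, n, phi,
#'   prevalences).
#' @export
select_num_clusters <- function(runs, data) {
  stopifnot(length(runs) >= 1)
  zs <- vapply(runs, function(r) r$num_clusters, 0L)
  ord <- order(zs)
  runs <- runs[ord]; zs <- zs[ord]
  idx <- vapply(runs, sdbw_of_fit, 0, data = data)
  report <- data.frame(
    num_clusters = zs, sdbw = idx,
    log_posterior = vapply(runs, function(r) r$log_posterior, 0),
    n = vapply(runs, function(r) r$params$n, 0),
    phi = vapply(runs, function(r) r$params$phi, 0),
    prevalences = vapply(runs, function(r)
      paste(sprintf("%.3f", 1 - r$params$s), collapse = ","), ""))
  pick <- if (all(is.na(idx))) 1L else which.min(idx)  # which.min skips NA
  list(selected = runs[[pick]], index = idx[pick], report = report)
}
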