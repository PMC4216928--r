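#' Single-nucleus LOH classification
#'
#' Targeted single-nucleus sequencing of an LOH event yields, per nucleus,
#' reference/alternate counts at the event's heterozygous SNP positions.
#' Whole-genome amplification causes allelic dropout — one allele failing
#' to amplify at a truly heterozygous site — which mimics LOH. The
#' classifier controls for this with two tests calibrated on normal
#' nuclei: a one-tailed binomial test on the number of homozygous-looking
#' positions against the expected dropout rate, and a rank-sum test of the
#' event's symmetric allelic ratios against the heterozygous reference
#' distribution. An event in a nucleus is called LOH when the maximum of
#' the two Benjamini-Hochberg-adjusted p-values falls below `alpha`.
#'
#' @name scloh
NULL

# Per-position zygosity: homozygous when the minor-allele fraction falls
# below `hom_threshold` at depth >= `min_depth`; NA below adequate depth.
position_zygosity <- function(ref, alt, min_depth = 10L,
                              hom_threshold = 0.1) {
  depth <- ref + alt
  maf <- ifelse(depth > 0, pmin(ref, alt) / depth, NA_real_)
  ifelse(depth >= min_depth, maf < hom_threshold, NA)
}

#' Expected allelic dropout rate from normal nuclei
#'
#' Fraction of adequate-coverage positions over known-heterozygous events
#' in normal nuclei that look homozygous — the rate at which
#' amplification alone produces a homozygous signal.
#'
#' @param normal_data Long-format data frame over normal nuclei:
#'   `nucleus`, `event`, `position`, `ref_count`, `alt_count`.
#' @param min_depth Coverage required to assess a position (default 10).
#' @param hom_threshold Minor-allele fraction below which a position is
#'   called homozygous (default 0.1).
#' @return Dropout rate in \[0, 1\].
#' @export
estimate_dropout_rate <- function(normal_data, min_depth = 10L,
                                  hom_threshold = 0.1) {
  hom <- position_zygosity(normal_data$ref_count, normal_data$alt_count,
                           min_depth, hom_threshold)
  if (!any(!is.na(hom)))
    stop("no adequate-coverage positions in the normal nuclei",
         call. = FALSE)
  mean(hom, na.rm = TRUE)
}

#' Heterozygous allelic-ratio reference sample from normal nuclei
#'
#' Pools the symmetric allelic ratios of adequate-coverage positions in
#' normal nuclei that are called heterozygous (dropout positions are
#' excluded: the dropout process is handled by the binomial test, and the
#' reference should represent the heterozygous signal). Kept as the
#' empirical sample for the rank-sum test.
#'
#' @inheritParams estimate_dropout_rate
#' @return Numeric vector of symmetric ratios.
#' @export
estimate_har <- function(normal_data, min_depth = 10L,
                         hom_threshold = 0.1) {
  depth <- normal_data$ref_count + normal_data$alt_count
  hom <- position_zygosity(normal_data$ref_count, normal_data$alt_count,
                           min_depth, hom_threshold)
  keep <- !is.na(hom) & !hom
  if (!any(keep))
    stop("no heterozygous adequate-coverage positions in the normal nuclei",
         call. = FALSE)
  symmetric_ratio(normal_data$ref_count[keep], depth[keep])
}

#' One-tailed binomial dropout test
#'
#' Null hypothesis: the proportion of homozygous positions in the event
#' is not greater than the expected dropout rate.
#' `p = P(X >= k_hom), X ~ Binomial(m, dor)`.
#'
#' @param k_hom Homozygous positions observed.
#' @param m Assessable positions.
#' @param dor Expected dropout rate.
#' @return One-tailed p-value.
#' @export
dropout_binomial_test <- function(k_hom, m, dor) {
  stopifnot(k_hom >= 0, k_hom <= m, dor >= 0, dor <= 1)
  stats::pbinom(k_hom - 1, m, dor, lower.tail = FALSE)
}

#' Rank-sum test of event allelic ratios against the reference
#'
#' Two-sample Wilcoxon rank-sum p-value comparing the nucleus's
#' symmetric allelic ratios over the event positions with the
#' heterozygous reference sample. Requires at least two observations per
#' side; otherwise returns `NA` (the event routes to "unknown").
#'
#' @param ratios Symmetric allelic ratios at the event positions.
#' @param har Reference sample from [estimate_har()].
#' @return Two-sided p-value, or `NA` when not computable.
#' @export
allelic_ratio_test <- function(ratios, har) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 2L || length(har) < 2L) return(NA_real_)
  suppressWarnings(stats::wilcox.test(ratios, har, exact = FALSE)$p.value)
}

#' Classify nucleus-by-event LOH status
#'
#' Runs both tests for every nucleus-by-event combination in the batch,
#' Benjamini-Hochberg-adjusts each test's p-values across the whole
#' batch, and calls LOH when the maximum of the two adjusted p-values is
#' below `alpha`. Non-significant combinations are HET when at least one
#' heterozygous position was observed, otherwise unknown; combinations
#' where either test is not computable are unknown.
#'
#' @param data Long-format data frame over tumor nuclei: `nucleus`,
#'   `event`, `position`, `ref_count`, `alt_count`.
#' @param dor Expected dropout rate ([estimate_dropout_rate()]).
#' @param har Heterozygous reference sample ([estimate_har()]).
#' @param alpha FDR threshold (default 0.05).
#' @param min_depth,hom_threshold Zygosity thresholds, as in
#'   [estimate_dropout_rate()].
#' @return Data frame with one row per nucleus-by-event: position counts,
#'   raw and adjusted p-values, and `status` in `{"LOH", "HET",
#'   "unknown"}`. Classification is invariant to the input row order.
#' @export
classify_loh_events <- function(data, dor, har, alpha = 0.05,
                                min_depth = 10L, hom_threshold = 0.1) {
  key <- interaction(data$nucleus, data$event, drop = TRUE, sep = "\r")
  groups <- split(seq_len(nrow(data)), key)
  # canonical order so results do not depend on input order
  groups <- groups[order(names(groups))]
  res <- lapply(groups, function(idx) {
    d <- data[idx, , drop = FALSE]
    hom <- position_zygosity(d$ref_count, d$alt_count, min_depth,
                             hom_threshold)
    m <- sum(!is.na(hom))
    k <- sum(hom, na.rm = TRUE)
    depth <- d$ref_count + d$alt_count
    ok <- depth >= min_depth
    ratios <- symmetric_ratio(d$ref_count[ok], depth[ok])
    data.frame(nucleus = d$nucleus[1], event = d$event[1],
               n_positions = nrow(d), n_adequate = m, n_hom = k,
               p_dropout = if (m > 0) dropout_binomial_test(k, m, dor)
                           else NA_real_,
               p_ratio = allelic_ratio_test(ratios, har),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res$q_dropout <- stats::p.adjust(res$p_dropout, method = "BH")
  res$q_ratio <- stats::p.adjust(res$p_ratio, method = "BH")
  qmax <- pmax(res$q_dropout, res$q_ratio)
  het_seen <- res$n_hom < res$n_adequate & res$n_adequate > 0
  res$status <- ifelse(is.na(res$p_dropout) | is.na(res$p_ratio), "unknown",
                ifelse(qmax < alpha, "LOH",
                ifelse(het_seen, "HET", "unknown")))
  res
}

#' Designate nuclei as tumor or normal from somatic-mutation status
#'
#' A nucleus is typed as tumor when at least one assayed somatic marker
#' (e.g. a truncal point mutation) shows mutant reads at adequate depth.
#'
#' @param mutation_data Data frame: `nucleus`, `position`, `ref_count`,
#'   `alt_count` at somatic marker positions.
#' @param min_depth Depth required to assess a marker (default 10).
#' @param min_alt Mutant reads required to call the marker present
#'   (default 2).
#' @return Data frame with `nucleus` and `cell_type` (`"tumor"`,
#'   `"normal"`, or `"unknown"` when no marker had adequate depth).
#' @export
assign_cell_types <- function(mutation_data, min_depth = 10L,
                              min_alt = 2L) {
  per <- split(mutation_data, mutation_data$nucleus)
  res <- lapply(per, function(d) {
    depth <- d$ref_count + d$alt_count
    ok <- depth >= min_depth
    type <- if (!any(ok)) "unknown"
            else if (any(d$alt_count[ok] >= min_alt)) "tumor"
            else "normal"
    data.frame(nucleus = d$nucleus[1], cell_type = type,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
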