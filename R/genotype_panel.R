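#' Allele-specific genotype state panel
#'
#' Enumerates the somatic genotype states used by the copy-number/LOH model:
#' every pair (c, k) of total copy number `c` and reference-allele copies
#' `k`, with `0 <= c <= max_copy` and `0 <= k <= c`. All zero-copy states
#' collapse to a single homozygous-deletion state (label `"-"`). Each state
#' is annotated with a call class describing the type of aberration:
#'
#' * `HOMD` homozygous deletion (c = 0)
#' * `DLOH` hemizygous deletion LOH (c = 1)
#' * `NLOH` copy-neutral LOH (c = 2, k in 0 or 2)
#' * `HET`  diploid heterozygous, the sole neutral state (c = 2, k = 1)
#' * `GAIN` single-copy gain (c = 3, one allele duplicated)
#' * `ALOH` amplified LOH (c >= 3, all copies from one allele)
#' * `ASCNA` allele-specific amplification (c >= 4, minor allele single copy)
#' * `BCNA` balanced amplification (c even >= 4, k = c/2)
#' * `UBCNA` unbalanced amplification (c = 5, k in 2 or 3)
#'
#' With the default `max_copy = 5` the panel holds 21 states.
#'
#' @param max_copy Maximum total copy number modelled (integer >= 2,
#'   default 5).
#' @return A data frame of class `genotype_panel` with columns `label`,
#'   `copy_number`, `ref_copies`, `call_class`, ordered by copy number then
#'   reference copies.
#' @examples
#' panel <- build_genotype_panel()
#' nrow(panel)                      # 21
#' subset(panel, call_class == "HET")
#' @export
build_genotype_panel <- function(max_copy = 5L) {
  if (!is.numeric(max_copy) || length(max_copy) != 1L || is.na(max_copy) ||
      max_copy < 2) {
    stop("'max_copy' must be a single integer >= 2", call. = FALSE)
  }
  max_copy <- as.integer(max_copy)
  cc <- unlist(lapply(1:max_copy, function(c) rep.int(c, c + 1L)))
  kk <- unlist(lapply(1:max_copy, function(c) 0:c))
  cc <- c(0L, cc)
  kk <- c(0L, kk)
  label <- ifelse(cc == 0L, "-", paste0(strrep("A", kk), strrep("B", cc - kk)))
  cls <- mapply(classify_genotype, cc, kk)
  panel <- data.frame(label = label, copy_number = cc, ref_copies = kk,
                      call_class = cls, stringsAsFactors = FALSE)
  attr(panel, "max_copy") <- max_copy
  class(panel) <- c("genotype_panel", "data.frame")
  panel
}

# Call class for a (copy number, ref copies) pair; minor count m = min(k, c-k)
classify_genotype <- function(c, k) {
  m <- min(k, c - k)
  if (c == 0L) return("HOMD")
  if (c == 1L) return("DLOH")
  if (c == 2L) return(if (k == 1L) "HET" else "NLOH")
  if (m == 0L) return("ALOH")
  if (c == 3L) return("GAIN")
  if (m == 1L) return("ASCNA")
  if (2L * m == c) return("BCNA")
  "UBCNA"
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", nrow(x), "states, max copy number",
      attr(x, "max_copy"), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a genotype panel as tab-delimited text
#'
#' @param panel A [build_genotype_panel()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expected depth log ratio for a genotype at a given cellular prevalence
#'
#' The observed coverage at a locus aggregates three cell populations:
#' normal cells (proportion `n`, copy number 2), tumor cells without the
#' event (proportion `(1-n)*s_z`, copy number 2) and tumor cells carrying
#' the event (proportion `(1-n)*(1-s_z)`, copy number `c_g`). The expected
#' log2 ratio against the matched normal is the aggregate copy number over
#' the sample-average copy number `n*2 + (1-n)*phi`, where `phi` is the
#' average tumor ploidy. When the aggregate reaches zero (homozygous
#' deletion at full prevalence and no contamination) it is floored at
#' `copy_floor` copies so the mean stays finite.
#'
#' @param c_g Tumor copy number of the genotype (non-negative; vectorised).
#' @param s_z Proportion of tumor cells *without* the event, in \[0, 1\]
#'   (`1 - s_z` is the tumor cellular prevalence).
#' @param n Normal-cell proportion in \[0, 1\].
#' @param phi Average tumor ploidy (> 0).
#' @param copy_floor Lower bound on the aggregate copy number (default 0.05).
#' @return Expected log2 ratio (vectorised over the inputs).
#' @examples
#' logratio_mean(1, s_z = 0, n = 0.25, phi = 2)   # hemizygous loss, clonal
#' logratio_mean(3, s_z = 0.5, n = 0, phi = 2)    # gain at 50% prevalence
#' @export
logratio_mean <- function(c_g, s_z, n, phi, copy_floor = 0.05) {
  stopifnot(all(c_g >= 0), all(s_z >= 0 & s_z <= 1), all(n >= 0 & n <= 1))
  if (any(phi <= 0)) stop("'phi' must be positive", call. = FALSE)
  agg <- n * 2 + (1 - n) * s_z * 2 + (1 - n) * (1 - s_z) * c_g
  agg <- pmax(agg, copy_floor)
  log2(agg / (n * 2 + (1 - n) * phi))
}

#' Expected reference-allele fraction for a genotype at a given prevalence
#'
#' Binomial success parameter for the tumor reference read count at a
#' germline heterozygous SNP: the reference-copy mass contributed by the
#' three populations over their total copy mass. Normal and event-free
#' tumor cells are diploid heterozygous (one reference copy of two); event
#' cells contribute `c_g * r_g` reference copies out of `c_g`, where
#' `r_g = k_g / c_g`. For the homozygous deletion the event population
#' contributes nothing to either term. The result is clamped to
#' `[eps, 1 - eps]` to absorb sequencing error at homozygous states.
#'
#' @param c_g Tumor copy number (vectorised).
#' @param k_g Reference-allele copies, `0 <= k_g <= c_g`.
#' @param s_z Proportion of tumor cells without the event.
#' @param n Normal-cell proportion.
#' @param eps Sequencing-error clamp (default 0.01).
#' @return Expected reference fraction, clamped to `[eps, 1 - eps]`.
#' @examples
#' allelic_ratio_param(2, 1, s_z = 0.3, n = 0.2)  # balanced: 0.5
#' allelic_ratio_param(1, 1, s_z = 0, n = 0.25)   # retained A allele: 0.8
#' @export
allelic_ratio_param <- function(c_g, k_g, s_z, n, eps = 0.01) {
  stopifnot(all(k_g >= 0), all(k_g <= c_g),
            all(s_z >= 0 & s_z <= 1), all(n >= 0 & n <= 1))
  num <- n * 1 + (1 - n) * s_z * 1 + (1 - n) * (1 - s_z) * k_g
  den <- n * 2 + (1 - n) * s_z * 2 + (1 - n) * (1 - s_z) * c_g
  w <- ifelse(den > 0, num / den, 0.5)
  pmin(pmax(w, eps), 1 - eps)
}

#' Expected transcriptome allelic ratio under deletion LOH
#'
#' For a hemizygous-deletion LOH event at sample cellular prevalence
#' `p = (1-n)(1-s_z)`, assuming expression proportional to copy number,
#' cells with the event express only the retained allele (1 of 1 copy) and
#' all other cells express both alleles (1 of 2 reference copies), so the
#' expected reference-allele fraction in RNA-seq reads over the retained
#' allele is `1 / (2 - p)`: 0.5 with no LOH cells, 1 when every cell is
#' hemizygous.
#'
#' @param n Normal-cell proportion.
#' @param s_z Proportion of tumor cells without the event.
#' @return Expected retained-allele expression fraction in \[0.5, 1\].
#' @export
expected_tar <- function(n, s_z) {
  stopifnot(all(n >= 0 & n <= 1), all(s_z >= 0 & s_z <= 1))
  p <- (1 - n) * (1 - s_z)
  1 / (2 - p)
}

#' Clonal cluster summary from model parameters
#'
#' @param s Vector of per-cluster proportions of tumor cells without the
#'   event (`s_z`), one per cluster.
#' @param n Normal-cell proportion (used for sample prevalence).
#' @return Data frame with cluster index, `s_z`, tumor cellular prevalence
#'   `1 - s_z` and sample cellular prevalence `(1-n)(1-s_z)`, ordered by
#'   decreasing tumor prevalence.
#' @export
clonal_clusters <- function(s, n) {
  stopifnot(all(s >= 0 & s <= 1), n >= 0, n <= 1)
  ord <- order(s)
  s <- s[ord]
  data.frame(cluster = seq_along(s), s_z = s,
             tumor_prevalence = 1 - s,
             sample_prevalence = (1 - n) * (1 - s))
}

#' Global model parameter container
#'
#' @param n Normal proportion in \[0, 1\].
#' @param phi Average tumor ploidy (> 0).
#' @param s Vector of per-cluster `s_z` values in \[0, 1\].
#' @param var Per-genotype log-ratio variance vector (positive), one entry
#'   per panel state.
#' @return A list of class `global_params`.
#' @export
global_params <- function(n, phi, s, var) {
  stopifnot(n >= 0, n <= 1, phi > 0, all(s >= 0 & s <= 1), all(var > 0))
  structure(list(n = n, phi = phi, s = as.numeric(s), var = as.numeric(var)),
            class = "global_params")
}

#' @export
print.global_params <- function(x, ...) {
  cat(sprintf("Global parameters: n = %.3f, phi = %.3f\n", x$n, x$phi))
  cat("  tumor prevalences (1 - s_z):",
      paste(sprintf("%.3f", 1 - x$s), collapse = ", "), "\n")
  cat(sprintf("  log-ratio sd range: [%.3f, %.3f]\n",
              sqrt(min(x$var)), sqrt(max(x$var))))
  invisible(x)
}
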