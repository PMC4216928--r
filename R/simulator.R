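#' Simulation configuration
#'
#' Describes a synthetic tumor-normal dataset: background diploid
#' heterozygous SNPs with segmental CNA/LOH events assigned to clonal
#' clusters. Signals are sampled from the model's own emission process:
#' per-SNP depth is Poisson around the target coverage scaled by the
#' aggregate copy ratio, reference counts are binomial at the
#' model-implied allelic ratio, and log ratios are Gaussian around the
#' model-implied mean. The log-ratio noise SD defaults to 0.25 at 30x and
#' scales with `1/sqrt(coverage)`.
#'
#' @param chrom_snps Named integer vector: SNPs per chromosome.
#' @param spacing_mean Mean inter-SNP spacing in bp (geometric; default
#'   1300, roughly the genome-wide density of heterozygous SNPs).
#' @param coverage Target haploid-normal coverage (default 30).
#' @param logratio_sd Log-ratio noise SD; default `0.25 * sqrt(30/coverage)`.
#' @param normal_prop Normal-cell proportion `n`.
#' @param ploidy Average tumor ploidy used in the log-ratio denominator.
#' @param cluster_prevalences Tumor cellular prevalence (1 - s_z) per
#'   clonal cluster, decreasing.
#' @param events Data frame: `chrom`, `start_snp` (1-based SNP index on
#'   that chromosome), `n_snps`, `genotype` (panel label, e.g. `"A"`,
#'   `"AAB"`), `cluster`.
#' @param max_copy Panel size for genotype labels.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom_snps, spacing_mean = 1300, coverage = 30,
                       logratio_sd = NULL, normal_prop = 0.25, ploidy = 2,
                       cluster_prevalences = 1, events = NULL,
                       max_copy = 5L, seed = 1L) {
  stopifnot(all(chrom_snps >= 1), coverage > 0,
            normal_prop >= 0, normal_prop <= 1, ploidy > 0,
            all(cluster_prevalences > 0 & cluster_prevalences <= 1))
  if (is.null(names(chrom_snps)))
    names(chrom_snps) <- paste0("chr", seq_along(chrom_snps))
  if (is.null(logratio_sd)) logratio_sd <- 0.25 * sqrt(30 / coverage)
  if (is.null(events))
    events <- data.frame(chrom = character(), start_snp = integer(),
                         n_snps = integer(), genotype = character(),
                         cluster = integer())
  panel <- build_genotype_panel(max_copy)
  if (!all(events$genotype %in% panel$label))
    stop("unknown genotype labels: ",
         paste(setdiff(events$genotype, panel$label), collapse = ", "),
         call. = FALSE)
  if (!all(events$cluster %in% seq_along(cluster_prevalences)))
    stop("event cluster indices outside the configured clusters",
         call. = FALSE)
  if (!all(events$chrom %in% names(chrom_snps)))
    stop("event chromosomes not in 'chrom_snps'", call. = FALSE)
  for (ch in unique(events$chrom)) {
    ev <- events[events$chrom == ch, , drop = FALSE]
    ev <- ev[order(ev$start_snp), , drop = FALSE]
    if (any(ev$start_snp < 1) ||
        any(ev$start_snp + ev$n_snps - 1 > chrom_snps[[ch]]))
      stop("event outside chromosome ", ch, call. = FALSE)
    if (nrow(ev) > 1 &&
        any(ev$start_snp[-1] <= (ev$start_snp + ev$n_snps - 1)[-nrow(ev)]))
      stop("overlapping events on ", ch, call. = FALSE)
  }
  structure(list(chrom_snps = chrom_snps, spacing_mean = spacing_mean,
                 coverage = coverage, logratio_sd = logratio_sd,
                 normal_prop = normal_prop, ploidy = ploidy,
                 cluster_prevalences = cluster_prevalences,
                 events = events, max_copy = max_copy,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample a synthetic dataset with ground truth
#'
#' @param config A [sim_config()].
#' @return List with `data` (per-SNP `chrom`, `pos`, `ref_count`, `depth`,
#'   `logratio`) and `truth` (class `truth_set`): per-SNP true genotype
#'   label/class/copy number/cluster and event id, the true global
#'   parameters, and a per-event table with expected tumor and sample
#'   prevalences.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- build_genotype_panel(config$max_copy)
  het <- which(panel$call_class == "HET")
  n <- config$normal_prop
  prev <- config$cluster_prevalences
  s <- 1 - prev
  chroms <- names(config$chrom_snps)
  rows <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    tn <- config$chrom_snps[[ch]]
    gaps <- stats::rgeom(tn, 1 / config$spacing_mean) + 1L
    pos <- cumsum(gaps)
    gidx <- rep.int(het, tn)
    zidx <- rep.int(1L, tn)
    eid <- rep(NA_character_, tn)
    ev <- config$events[config$events$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      span <- ev$start_snp[r]:(ev$start_snp[r] + ev$n_snps[r] - 1L)
      gidx[span] <- match(ev$genotype[r], panel$label)
      zidx[span] <- ev$cluster[r]
      eid[span] <- rownames(ev)[r]
    }
    cg <- panel$copy_number[gidx]
    kg <- panel$ref_copies[gidx]
    sz <- s[zidx]
    mu <- logratio_mean(cg, sz, n, config$ploidy)
    om <- allelic_ratio_param(cg, kg, sz, n)
    agg <- pmax(n * 2 + (1 - n) * sz * 2 + (1 - n) * (1 - sz) * cg, 0.05)
    depth <- stats::rpois(tn, config$coverage * agg / 2)
    ref <- stats::rbinom(tn, depth, om)
    l <- stats::rnorm(tn, mu, config$logratio_sd)
    rows[[ci]] <- data.frame(chrom = ch, pos = pos, ref_count = ref,
                             depth = depth, logratio = l,
                             genotype = gidx, cluster = zidx, event = eid,
                             stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  rownames(all) <- NULL
  data <- all[c("chrom", "pos", "ref_count", "depth", "logratio")]
  truth_snp <- data.frame(chrom = all$chrom, pos = all$pos,
                          label = panel$label[all$genotype],
                          call = panel$call_class[all$genotype],
                          copy_number = panel$copy_number[all$genotype],
                          cluster = all$cluster, event = all$event,
                          stringsAsFactors = FALSE)
  ev <- config$events
  events <- NULL
  if (nrow(ev)) {
    gi <- match(ev$genotype, panel$label)
    events <- data.frame(event = rownames(ev), chrom = ev$chrom,
                         start_snp = ev$start_snp, n_snps = ev$n_snps,
                         genotype = ev$genotype,
                         call = panel$call_class[gi],
                         copy_number = panel$copy_number[gi],
                         cluster = ev$cluster,
                         tumor_prevalence = prev[ev$cluster],
                         sample_prevalence = (1 - n) * prev[ev$cluster],
                         stringsAsFactors = FALSE)
  }
  truth <- structure(list(snps = truth_snp, events = events,
                          params = list(n = n, phi = config$ploidy, s = s,
                                        prevalences = prev)),
                     class = "truth_set")
  list(data = data, truth = truth)
}

# Place a set of event sizes on chromosomes, keeping at least `gap`
# background SNPs between events and from chromosome ends. Greedy: each
# event goes to the chromosome with the most free room.
place_events <- function(sizes, chrom_snps, gap = 1000L) {
  cursor <- rep(gap + 1L, length(chrom_snps))
  names(cursor) <- names(chrom_snps)
  chrom <- character(length(sizes))
  start <- integer(length(sizes))
  ord <- order(sizes, decreasing = TRUE)
  for (i in ord) {
    room <- chrom_snps - cursor - gap
    pick <- which.max(room)
    if (room[pick] < sizes[i])
      stop("chromosomes too short for the requested events", call. = FALSE)
    chrom[i] <- names(chrom_snps)[pick]
    start[i] <- cursor[pick]
    cursor[pick] <- cursor[pick] + sizes[i] + gap
  }
  data.frame(chrom = chrom, start_snp = start)
}

#' Spike-in benchmark scenario
#'
#' Builds the spike-in design: four deletions (hemizygous-deletion LOH,
#' genotype `"A"`) and four amplifications (single-copy gain, `"AAB"`)
#' for each event size in `sizes` up to 1000 SNPs, plus one deletion and
#' one amplification of 10,000 SNPs when requested, embedded in otherwise
#' diploid-heterozygous chromosomes and alternately assigned to two
#' clonal clusters (default tumor prevalences 0.52 and 0.39). With the
#' default sizes the scenario holds 26 events.
#'
#' @param sizes Event sizes in SNPs (subset of 10/100/1000/10000; any
#'   positive sizes accepted — sizes below 10000 get 4+4 events, 10000
#'   gets 1+1).
#' @param prevalences Tumor cellular prevalences of the two clusters.
#' @param chrom_snps SNPs per chromosome (default four chromosomes of
#'   37,500 SNPs, ~150k total).
#' @param normal_prop,coverage,seed Passed to [sim_config()].
#' @return A [sim_config()].
#' @export
build_spikein_scenario <- function(sizes = c(10, 100, 1000, 10000),
                                   prevalences = c(0.52, 0.39),
                                   chrom_snps = rep(37500L, 4),
                                   normal_prop = 0.25, coverage = 30,
                                   seed = 1L) {
  stopifnot(length(prevalences) == 2, all(sizes >= 1))
  reps <- ifelse(sizes >= 10000, 1L, 4L)
  ev_sizes <- unlist(mapply(function(sz, r) rep(sz, 2L * r), sizes, reps,
                            SIMPLIFY = FALSE))
  genotype <- unlist(mapply(function(sz, r)
    rep(c("A", "AAB"), each = r), sizes, reps, SIMPLIFY = FALSE))
  cluster <- unlist(mapply(function(sz, r) {
    if (r == 1L) c(1L, 2L) else rep_len(c(1L, 2L), 2L * r)
  }, sizes, reps, SIMPLIFY = FALSE))
  if (is.null(names(chrom_snps)))
    names(chrom_snps) <- paste0("chr", seq_along(chrom_snps))
  # keep events well separated; shrink the gap on small test genomes
  loc <- NULL
  for (gap in c(1000L, 500L, 250L, 100L)) {
    loc <- tryCatch(place_events(ev_sizes, chrom_snps, gap = gap),
                    error = function(e) NULL)
    if (!is.null(loc)) break
  }
  if (is.null(loc))
    stop("chromosomes too short for the requested events", call. = FALSE)
  events <- data.frame(chrom = loc$chrom, start_snp = loc$start_snp,
                       n_snps = as.integer(ev_sizes), genotype = genotype,
                       cluster = cluster, stringsAsFactors = FALSE)
  rownames(events) <- sprintf("ev%02d", seq_len(nrow(events)))
  sim_config(chrom_snps = chrom_snps, coverage = coverage,
             normal_prop = normal_prop, cluster_prevalences = prevalences,
             events = events, seed = seed)
}

#' Expected prevalences of an event in a multi-sample mixture
#'
#' When samples with known tumor cellularities are mixed at known
#' fractions, an event carried by a subset of the samples has sample
#' cellular prevalence equal to the tumor mass those samples contribute,
#' and tumor cellular prevalence equal to that mass over the total tumor
#' mass of the mixture.
#'
#' @param fractions Mixing fractions (sum to 1).
#' @param cellularities Tumor content of each sample.
#' @param member_mask Logical (or index) vector: which samples carry the
#'   event.
#' @return List with `sample_prevalence` and `tumor_prevalence`.
#' @examples
#' # equal merge of 80% and 70% cellularity tumors, event in sample a only
#' expected_prevalences(c(0.5, 0.5), c(0.8, 0.7), c(TRUE, FALSE))
#' @export
expected_prevalences <- function(fractions, cellularities, member_mask) {
  stopifnot(length(fractions) == length(cellularities),
            all(fractions >= 0), all(cellularities >= 0),
            all(cellularities <= 1))
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("mixing fractions must sum to 1", call. = FALSE)
  if (is.logical(member_mask)) {
    stopifnot(length(member_mask) == length(fractions))
    mask <- member_mask
  } else {
    mask <- seq_along(fractions) %in% member_mask
  }
  total <- sum(fractions * cellularities)
  if (total <= 0)
    stop("mixture contains no tumor cells; prevalence undefined",
         call. = FALSE)
  samp <- sum(fractions[mask] * cellularities[mask])
  list(sample_prevalence = samp, tumor_prevalence = samp / total)
}

# Default event layout for the two-sample mixture scenario: shared clonal
# events plus events unique to each sample, mixed sizes and types.
default_mixture_events <- function() {
  list(shared = data.frame(genotype = c("A", "AAB", "AA"),
                           n_snps = c(600L, 500L, 400L)),
       unique_a = data.frame(genotype = c("A", "AAB", "AA", "A"),
                             n_snps = c(500L, 600L, 500L, 400L)),
       unique_b = data.frame(genotype = c("A", "AAB", "AA", "A"),
                             n_snps = c(600L, 500L, 400L, 500L)))
}

#' Serial two-sample mixture scenario
#'
#' Emulates mixing two tumor samples of known cellularity at given
#' fractions: events shared by both samples are clonal (tumor prevalence
#' 1) while events unique to one sample sit at the tumor prevalence given
#' by [expected_prevalences()]. The normal proportion of the mixture is
#' `1 - sum(fractions * cellularities)`.
#'
#' @param fractions Length-2 mixing fractions summing to 1.
#' @param cellularities Length-2 tumor contents (defaults 0.67 and 0.56).
#' @param events List with data frames `shared`, `unique_a`, `unique_b`
#'   (columns `genotype`, `n_snps`); a default mixed layout is used when
#'   omitted.
#' @param chrom_snps SNPs per chromosome (default two chromosomes of
#'   10,000).
#' @param coverage,seed Passed to [sim_config()].
#' @return A [sim_config()] whose cluster 1 holds the shared events.
#' @export
build_serial_mixture_scenario <- function(fractions,
                                          cellularities = c(0.67, 0.56),
                                          events = default_mixture_events(),
                                          chrom_snps = rep(10000L, 2),
                                          coverage = 30, seed = 1L) {
  stopifnot(length(fractions) == 2, all(fractions > 0), all(fractions < 1))
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("mixing fractions must sum to 1", call. = FALSE)
  n <- 1 - sum(fractions * cellularities)
  prev_a <- expected_prevalences(fractions, cellularities,
                                 c(TRUE, FALSE))$tumor_prevalence
  prev_b <- expected_prevalences(fractions, cellularities,
                                 c(FALSE, TRUE))$tumor_prevalence
  tab <- rbind(
    data.frame(genotype = events$shared$genotype,
               n_snps = events$shared$n_snps, cluster = 1L),
    data.frame(genotype = events$unique_a$genotype,
               n_snps = events$unique_a$n_snps, cluster = 2L),
    data.frame(genotype = events$unique_b$genotype,
               n_snps = events$unique_b$n_snps, cluster = 3L))
  prevs <- c(1, prev_a, prev_b)
  # clusters must be ordered by decreasing prevalence
  ord <- order(prevs, decreasing = TRUE)
  tab$cluster <- match(tab$cluster, ord)
  prevs <- prevs[ord]
  if (is.null(names(chrom_snps)))
    names(chrom_snps) <- paste0("chr", seq_along(chrom_snps))
  # interleave clusters along the placement order so each chromosome sees
  # a mix of shared and unique events
  tab <- tab[order(seq_len(nrow(tab)) %% 3, tab$cluster), , drop = FALSE]
  loc <- place_events(tab$n_snps, chrom_snps, gap = 400L)
  evdf <- data.frame(chrom = loc$chrom, start_snp = loc$start_snp,
                     n_snps = tab$n_snps, genotype = tab$genotype,
                     cluster = tab$cluster, stringsAsFactors = FALSE)
  rownames(evdf) <- sprintf("mix%02d", seq_len(nrow(evdf)))
  sim_config(chrom_snps = chrom_snps, coverage = coverage,
             normal_prop = n, cluster_prevalences = prevs,
             events = evdf, seed = seed)
}
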