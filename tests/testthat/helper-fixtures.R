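# Shared fixture builders: everything is generated in code at test time.

# Random toy chain for comparing the HMM recursions against exhaustive
# path enumeration.
random_toy_chain <- function(T_len, K) {
  loge <- matrix(stats::rnorm(T_len * K, sd = 1.5), T_len, K)
  P <- matrix(stats::runif(K * K) + 0.05, K, K)
  P <- P / rowSums(P)
  init <- stats::runif(K) + 0.05
  init <- init / sum(init)
  list(loge = loge, P = P, init = init)
}

# Log-probability of every path of a toy chain (exhaustive enumeration).
enumerate_paths <- function(chain) {
  T_len <- nrow(chain$loge)
  K <- ncol(chain$loge)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
  lp <- apply(paths, 1, function(s) {
    v <- log(chain$init[s[1]]) + chain$loge[1, s[1]]
    for (t in seq_len(T_len)[-1])
      v <- v + log(chain$P[s[t - 1], s[t]]) + chain$loge[t, s[t]]
    v
  })
  list(paths = paths, logprob = lp)
}

# Small two-cluster simulation used by several EM tests.
two_cluster_sim <- function(n = 0.3, prevalences = c(0.9, 0.4),
                            snps_per_chrom = 10000L, event_snps = 800L,
                            events_per_chrom = 5L, seed = 42L) {
  gap <- max(100L, event_snps %/% 2L)
  starts <- seq(gap, by = event_snps + gap,
                length.out = events_per_chrom)
  stopifnot(max(starts) + event_snps <= snps_per_chrom)
  ev <- data.frame(chrom = rep(c("chr1", "chr2"), each = events_per_chrom),
                   start_snp = rep(starts, 2), n_snps = event_snps,
                   genotype = rep_len(c("A", "AAB", "AA", "A", "AAB"),
                                      2 * events_per_chrom),
                   cluster = rep_len(seq_along(prevalences),
                                     2 * events_per_chrom))
  cfg <- sim_config(chrom_snps = c(chr1 = snps_per_chrom,
                                   chr2 = snps_per_chrom),
                    normal_prop = n, cluster_prevalences = prevalences,
                    events = ev, seed = seed)
  simulate_dataset(cfg)
}

# Synthetic single-nucleus batch: `n_nuclei` nuclei over one event with
# `m` positions each, drawn either as heterozygous (balanced with allelic
# dropout at rate `dor`) or as hemizygous (fully homozygous signal).
simulate_nuclei <- function(n_nuclei, m = 10L, depth = 40L, dor = 0.28,
                            loh = FALSE, prefix = "nuc") {
  rows <- lapply(seq_len(n_nuclei), function(i) {
    if (loh) {
      ref <- stats::rbinom(m, depth, 0.98)
    } else {
      dropped <- stats::runif(m) < dor
      p <- ifelse(dropped, sample(c(0.02, 0.98), m, replace = TRUE), 0.5)
      ref <- stats::rbinom(m, depth, p)
    }
    data.frame(nucleus = paste0(prefix, i), event = "ev1",
               position = seq_len(m) * 100L,
               ref_count = ref, alt_count = depth - ref,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
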