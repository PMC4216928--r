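test_that("neutral background has zero mean log ratio and balanced alleles", {
  cfg <- sim_config(chrom_snps = c(chr1 = 50000L), normal_prop = 0.3,
                    seed = 3)
  sim <- simulate_dataset(cfg)
  expect_lt(abs(mean(sim$data$logratio)), 0.01)
  expect_lt(abs(mean(sim$data$ref_count / sim$data$depth, na.rm = TRUE)
                - 0.5), 0.01)
  expect_true(all(sim$truth$snps$call == "HET"))
})

test_that("a clonal deletion in a pure tumor reaches the clamped ratio", {
  ev <- data.frame(chrom = "chr1", start_snp = 200L, n_snps = 2000L,
                   genotype = "A", cluster = 1L)
  cfg <- sim_config(chrom_snps = c(chr1 = 3000L), normal_prop = 0,
                    cluster_prevalences = 1, events = ev, seed = 5)
  sim <- simulate_dataset(cfg)
  inside <- !is.na(sim$truth$snps$event)
  r <- sim$data$ref_count[inside] / sim$data$depth[inside]
  expect_equal(mean(r, na.rm = TRUE), 0.99, tolerance = 0.01)
})

test_that("event moments converge to the emission parameters", {
  # law of large numbers at 1000 SNPs: means within 3 standard errors
  ev <- data.frame(chrom = "chr1", start_snp = 150L, n_snps = 1000L,
                   genotype = "AAB", cluster = 1L)
  cfg <- sim_config(chrom_snps = c(chr1 = 1400L), normal_prop = 0.25,
                    cluster_prevalences = 0.6, events = ev, seed = 21)
  sim <- simulate_dataset(cfg)
  inside <- which(!is.na(sim$truth$snps$event))
  mu <- logratio_mean(3, 0.4, 0.25, 2)
  om <- allelic_ratio_param(3, 2, 0.4, 0.25)
  l <- sim$data$logratio[inside]
  expect_lt(abs(mean(l) - mu), 3 * sd(l) / sqrt(length(l)))
  ratio <- sim$data$ref_count[inside] / sim$data$depth[inside]
  expect_lt(abs(mean(ratio) - om), 3 * sd(ratio) / sqrt(length(ratio)))
})

test_that("the same seed reproduces the dataset exactly", {
  cfg <- build_spikein_scenario(sizes = c(10, 100),
                                chrom_snps = rep(5000L, 2), seed = 9)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a, b)
})

test_that("overlapping events are rejected", {
  ev <- data.frame(chrom = "chr1", start_snp = c(100L, 150L),
                   n_snps = c(100L, 50L), genotype = "A", cluster = 1L)
  expect_error(sim_config(chrom_snps = c(chr1 = 1000L),
                          cluster_prevalences = 1, events = ev, seed = 1),
               "overlap")
})

test_that("spike-in scenario holds the documented event layout", {
  cfg <- build_spikein_scenario(seed = 1)
  expect_equal(nrow(cfg$events), 26L)
  expect_equal(sum(cfg$events$n_snps == 10), 8L)
  expect_equal(sum(cfg$events$n_snps == 100), 8L)
  expect_equal(sum(cfg$events$n_snps == 1000), 8L)
  expect_equal(sum(cfg$events$n_snps == 10000), 2L)
  expect_equal(sort(unique(cfg$events$genotype)), c("A", "AAB"))
  expect_equal(cfg$cluster_prevalences, c(0.52, 0.39))
  # both clusters are used for each size class below 10000
  for (sz in c(10, 100, 1000)) {
    sub <- cfg$events[cfg$events$n_snps == sz, ]
    expect_setequal(unique(sub$cluster), 1:2)
  }
  # single-size variant
  expect_equal(nrow(build_spikein_scenario(sizes = 100,
                                           chrom_snps = rep(3000L, 2),
                                           seed = 1)$events), 8L)
})

test_that("spike-in events keep at least 100 background SNPs apart", {
  cfg <- build_spikein_scenario(seed = 2)
  for (ch in unique(cfg$events$chrom)) {
    ev <- cfg$events[cfg$events$chrom == ch, ]
    ev <- ev[order(ev$start_snp), ]
    if (nrow(ev) > 1) {
      gaps <- ev$start_snp[-1] - (ev$start_snp + ev$n_snps)[-nrow(ev)]
      expect_true(all(gaps >= 100))
    }
  }
})

test_that("expected prevalences reproduce the mixture arithmetic", {
  # equal merge of 80%/70% cellularity samples, event in sample a only:
  # 40% of the merged sample, 53% of tumor cells
  p <- expected_prevalences(c(0.5, 0.5), c(0.8, 0.7), c(TRUE, FALSE))
  expect_equal(p$sample_prevalence, 0.40)
  expect_equal(p$tumor_prevalence, 0.40 / 0.75)
  # shared event: 75% of the sample, all tumor cells
  s <- expected_prevalences(c(0.5, 0.5), c(0.8, 0.7), c(TRUE, TRUE))
  expect_equal(s$sample_prevalence, 0.75)
  expect_equal(s$tumor_prevalence, 1.0)
  # 10%:90% mixture at 67%/56% cellularity: minor sample contributes 0.07
  m <- expected_prevalences(c(0.1, 0.9), c(0.67, 0.56), c(TRUE, FALSE))
  expect_equal(round(m$sample_prevalence, 2), 0.07)
  expect_equal(m$tumor_prevalence, 0.067 / 0.571, tolerance = 1e-3)
  # degenerate mixture errors
  expect_error(expected_prevalences(c(0.5, 0.5), c(0, 0), c(TRUE, FALSE)),
               "no tumor")
  expect_error(expected_prevalences(c(0.6, 0.6), c(0.8, 0.7),
                                    c(TRUE, FALSE)), "sum to 1")
})

test_that("serial mixture scenario encodes the expected populations", {
  cfg <- build_serial_mixture_scenario(c(0.1, 0.9), seed = 4)
  expect_equal(cfg$normal_prop, 1 - (0.1 * 0.67 + 0.9 * 0.56))
  expect_equal(max(cfg$cluster_prevalences), 1.0)
  expect_equal(sort(cfg$cluster_prevalences),
               sort(c(1, 0.067 / 0.571, 0.504 / 0.571)), tolerance = 1e-3)
  # swapping the samples at equal fractions swaps the unique prevalences
  a <- build_serial_mixture_scenario(c(0.5, 0.5),
                                     cellularities = c(0.8, 0.6), seed = 1)
  b <- build_serial_mixture_scenario(c(0.5, 0.5),
                                     cellularities = c(0.6, 0.8), seed = 1)
  expect_equal(sort(a$cluster_prevalences), sort(b$cluster_prevalences))
  # the three shared events sit in the prevalence-1 cluster
  expect_equal(sum(cfg$cluster_prevalences[cfg$events$cluster] == 1), 3L)
})

test_that("truth events carry consistent prevalence annotation", {
  cfg <- build_spikein_scenario(sizes = c(100),
                                chrom_snps = rep(3000L, 2), seed = 8)
  sim <- simulate_dataset(cfg)
  ev <- sim$truth$events
  expect_equal(ev$tumor_prevalence,
               cfg$cluster_prevalences[ev$cluster])
  expect_equal(ev$sample_prevalence,
               (1 - cfg$normal_prop) * ev$tumor_prevalence)
  # per-SNP truth agrees with the event table
  for (i in seq_len(nrow(ev))) {
    idx <- sim$truth$snps$event == ev$event[i] &
      !is.na(sim$truth$snps$event)
    expect_equal(sum(idx), ev$n_snps[i])
    expect_true(all(sim$truth$snps$cluster[idx] == ev$cluster[i]))
  }
})
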