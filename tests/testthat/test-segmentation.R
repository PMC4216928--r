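# Minimal call-table builder for segmentation tests.
calls_from_states <- function(call, copy_number, cluster,
                              chrom = "chr1") {
  n <- length(call)
  data.frame(chrom = chrom, pos = seq_len(n) * 1000L,
             ref_count = 15L, depth = 30L, allelic_ratio = 0.5,
             logratio = 0, call = call, copy_number = copy_number,
             cluster = cluster, tumor_prevalence = 1 - 0.2 * cluster,
             sample_prevalence = 0.7 * (1 - 0.2 * cluster),
             outlier = FALSE, stringsAsFactors = FALSE)
}

test_that("a constant path collapses to one segment", {
  calls <- calls_from_states(rep("HET", 100), rep(2L, 100), rep(1L, 100))
  seg <- decode_to_segments(calls)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 100L)
  expect_equal(seg$start, 1000L)
  expect_equal(seg$end, 100000L)
})

test_that("state changes split segments at the right boundaries", {
  calls <- calls_from_states(
    c(rep("HET", 50), rep("DLOH", 50), rep("HET", 20)),
    c(rep(2L, 50), rep(1L, 50), rep(2L, 20)),
    c(rep(1L, 50), rep(2L, 50), rep(1L, 20)))
  seg <- decode_to_segments(calls)
  expect_equal(nrow(seg), 3L)
  expect_equal(seg$n_snps, c(50L, 50L, 20L))
  expect_equal(seg$start, c(1L, 51L, 101L) * 1000L)
  expect_equal(seg$end, c(50L, 100L, 120L) * 1000L)
  expect_equal(seg$call, c("HET", "DLOH", "HET"))
})

test_that("expanding segments reproduces the per-SNP path", {
  set.seed(6)
  # random piecewise-constant path over two chromosomes
  states <- data.frame(call = c("HET", "DLOH", "GAIN", "NLOH"),
                       copy_number = c(2L, 1L, 3L, 2L),
                       cluster = c(1L, 2L, 1L, 2L))
  pick <- unlist(lapply(sample(1:4, 12, replace = TRUE),
                        function(s) rep(s, sample(5:30, 1))))
  calls <- calls_from_states(states$call[pick], states$copy_number[pick],
                             states$cluster[pick])
  calls$chrom <- rep(c("chr1", "chr2"), length.out = nrow(calls))
  calls <- calls[order(calls$chrom, calls$pos), ]
  seg <- decode_to_segments(calls)
  # round trip: per-SNP expansion of segments equals the input
  expanded <- seg[rep(seq_len(nrow(seg)), seg$n_snps), ]
  expect_equal(expanded$call, calls$call)
  expect_equal(expanded$copy_number, calls$copy_number)
  expect_equal(expanded$cluster, calls$cluster)
  # partition: per-chromosome segment SNPs cover everything exactly once
  expect_equal(sum(seg$n_snps), nrow(calls))
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    expect_true(all(s$start[-1] > s$end[-nrow(s)]))
  }
})

test_that("outlier SNPs are bridged into flanking segments", {
  sim <- two_cluster_sim(snps_per_chrom = 1200L, event_snps = 300L,
                         events_per_chrom = 2L, seed = 11)
  fit <- suppressWarnings(em_fit(sim$data, 2, max_iter = 5))
  # force some outliers inside and at state boundaries
  fit$path$outlier[c(5, 50, 51, 700)] <- TRUE
  calls <- snp_calls(fit, sim$data)
  expect_false(any(is.na(calls$call)))
  # an outlier with identical flanks inherits that state
  expect_equal(calls$call[50], calls$call[49])
  expect_equal(calls$call[51], calls$call[52])
})

test_that("genome summary splits clonal and subclonal fractions", {
  calls <- calls_from_states(
    c(rep("GAIN", 20), rep("HET", 50), rep("DLOH", 30)),
    c(rep(3L, 20), rep(2L, 50), rep(1L, 30)),
    c(rep(1L, 20), rep(1L, 50), rep(2L, 30)))
  s <- summarize_genome(decode_to_segments(calls))
  expect_equal(s$frac_altered, 0.5)
  expect_equal(s$frac_clonal, 0.2)
  expect_equal(s$frac_subclonal, 0.3)
  # all-neutral decode
  het <- calls_from_states(rep("HET", 40), rep(2L, 40), rep(1L, 40))
  expect_equal(summarize_genome(decode_to_segments(het))$frac_altered, 0)
})

test_that("performance metrics follow confusion-matrix arithmetic", {
  n <- 300
  truth <- data.frame(chrom = "chr1", pos = seq_len(n) * 10L,
                      call = rep("HET", n), copy_number = rep(2L, n),
                      event = NA_character_, stringsAsFactors = FALSE)
  truth$call[1:100] <- "DLOH"
  truth$copy_number[1:100] <- 1L
  truth$event[1:100] <- "del1"
  pred <- truth[c("chrom", "pos", "call", "copy_number")]
  # perfect prediction: everything 1
  m <- performance_metrics(pred, truth)
  expect_equal(m$by_class$recall[m$by_class$class == "deletion"], 1)
  expect_equal(m$by_class$precision[m$by_class$class == "deletion"], 1)
  expect_equal(m$fpr, 0)
  expect_true(m$events$detected)
  # 80 of 100 deletion SNPs found, plus 20 false deletions
  pred2 <- pred
  pred2$call[81:100] <- "HET"; pred2$copy_number[81:100] <- 2L
  pred2$call[101:120] <- "DLOH"; pred2$copy_number[101:120] <- 1L
  m2 <- performance_metrics(pred2, truth)
  del <- m2$by_class[m2$by_class$class == "deletion", ]
  expect_equal(del$recall, 0.8)
  expect_equal(del$precision, 0.8)
  expect_equal(del$f_measure, 0.8)
  expect_equal(m2$events$recall, 0.8)
  expect_false(m2$events$detected)
  expect_equal(m2$fpr, 20 / 200)
})

test_that("F-measure equals the harmonic mean of precision and recall", {
  set.seed(12)
  n <- 400
  states <- data.frame(call = c("HET", "DLOH", "GAIN", "NLOH"),
                       copy_number = c(2L, 1L, 3L, 2L))
  ti <- sample(1:4, n, replace = TRUE, prob = c(.6, .15, .15, .1))
  pi_ <- ifelse(runif(n) < 0.75, ti, sample(1:4, n, replace = TRUE))
  truth <- data.frame(chrom = "chr1", pos = seq_len(n),
                      call = states$call[ti],
                      copy_number = states$copy_number[ti])
  pred <- data.frame(chrom = "chr1", pos = seq_len(n),
                     call = states$call[pi_],
                     copy_number = states$copy_number[pi_])
  m <- performance_metrics(pred, truth)$by_class
  m <- m[m$class != "overall" & !is.na(m$f_measure), ]
  expect_equal(m$f_measure,
               2 * m$precision * m$recall / (m$precision + m$recall))
})

test_that("no aberrant truth yields NA recall, mismatched sets error", {
  truth <- data.frame(chrom = "chr1", pos = 1:50, call = "HET",
                      copy_number = 2L)
  pred <- truth
  m <- performance_metrics(pred, truth)
  expect_true(is.na(m$by_class$recall[m$by_class$class == "deletion"]))
  expect_error(performance_metrics(pred[-1, ], truth), "differ")
})
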