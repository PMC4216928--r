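test_that("dropout rate is the homozygous fraction of adequate positions", {
  # balanced heterozygous signal everywhere: no dropout
  d <- data.frame(nucleus = "n1", event = "e1", position = 1:20,
                  ref_count = 15L, alt_count = 15L)
  expect_equal(estimate_dropout_rate(d), 0)
  # 28 of 100 positions homozygous
  d2 <- data.frame(nucleus = "n1", event = "e1", position = 1:100,
                   ref_count = c(rep(30L, 28), rep(15L, 72)),
                   alt_count = c(rep(0L, 28), rep(15L, 72)))
  expect_equal(estimate_dropout_rate(d2), 0.28)
  # 48 of 100
  d3 <- d2
  d3$ref_count[29:48] <- 30L
  d3$alt_count[29:48] <- 0L
  expect_equal(estimate_dropout_rate(d3), 0.48)
  # low-coverage positions are not assessed
  d4 <- data.frame(nucleus = "n1", event = "e1", position = 1:2,
                   ref_count = c(3L, 15L), alt_count = c(0L, 15L))
  expect_equal(estimate_dropout_rate(d4), 0)
  expect_error(estimate_dropout_rate(
    data.frame(nucleus = "n1", event = "e1", position = 1,
               ref_count = 2L, alt_count = 1L)), "adequate")
})

test_that("HAR reference excludes dropout positions", {
  d <- data.frame(nucleus = "n1", event = "e1", position = 1:10,
                  ref_count = c(rep(30L, 2), rep(18L, 8)),
                  alt_count = c(rep(0L, 2), rep(12L, 8)))
  har <- estimate_har(d)
  expect_length(har, 8)
  expect_equal(har, rep(0.6, 8))
})

test_that("dropout binomial test matches the closed-form tail", {
  expect_equal(dropout_binomial_test(0, 10, 0.28), 1.0)
  expect_equal(dropout_binomial_test(10, 10, 0.28), 0.28^10)
  # direct pmf summation oracle
  expect_equal(dropout_binomial_test(6, 10, 0.28),
               sum(dbinom(6:10, 10, 0.28)))
  expect_equal(round(dropout_binomial_test(6, 10, 0.28), 4), 0.0342)
})

test_that("rank-sum test flags shifted allelic ratios", {
  set.seed(30)
  har <- symmetric_ratio(rbinom(30, 40, 0.5), rep(40, 30))
  # identical values: no evidence of a shift
  expect_gt(allelic_ratio_test(har, har), 0.9)
  # all-homozygous ratios against a balanced reference
  expect_lt(allelic_ratio_test(rep(1.0, 10), har), 0.001)
  # single observation is not testable
  expect_true(is.na(allelic_ratio_test(1.0, har)))
})

test_that("classification separates LOH, HET and unknown nuclei", {
  set.seed(41)
  normal <- simulate_nuclei(8, dor = 0.2, prefix = "norm")
  dor <- estimate_dropout_rate(normal)
  har <- estimate_har(normal)
  batch <- rbind(simulate_nuclei(6, loh = TRUE, prefix = "loh"),
                 simulate_nuclei(6, dor = 0.2, prefix = "het"),
                 data.frame(nucleus = "low1", event = "ev1",
                            position = 1:5, ref_count = 2L,
                            alt_count = 1L))
  res <- classify_loh_events(batch, dor, har)
  expect_true(all(res$status[grepl("^loh", res$nucleus)] == "LOH"))
  expect_true(all(res$status[grepl("^het", res$nucleus)] == "HET"))
  expect_equal(res$status[res$nucleus == "low1"], "unknown")
  # fully homozygous nucleus at m = 10 has both adjusted p-values small
  loh_rows <- res[grepl("^loh", res$nucleus), ]
  expect_true(all(pmax(loh_rows$q_dropout, loh_rows$q_ratio) < 0.05))
})

test_that("classification is invariant to input row order", {
  set.seed(52)
  normal <- simulate_nuclei(6, dor = 0.25, prefix = "norm")
  dor <- estimate_dropout_rate(normal)
  har <- estimate_har(normal)
  batch <- rbind(simulate_nuclei(4, loh = TRUE, prefix = "loh"),
                 simulate_nuclei(4, dor = 0.25, prefix = "het"))
  res1 <- classify_loh_events(batch, dor, har)
  perm <- sample(nrow(batch))
  res2 <- classify_loh_events(batch[perm, ], dor, har)
  expect_equal(res1, res2)
})

test_that("false-LOH rate on null nuclei stays within the FDR level", {
  set.seed(63)
  normal <- simulate_nuclei(30, m = 12L, dor = 0.28, prefix = "norm")
  dor <- estimate_dropout_rate(normal)
  har <- estimate_har(normal)
  nulls <- simulate_nuclei(1000, m = 10L, dor = 0.28, prefix = "null")
  res <- classify_loh_events(nulls, dor, har)
  expect_lte(mean(res$status == "LOH"), 0.05)
})

test_that("hemizygous nuclei are detected with high sensitivity", {
  set.seed(74)
  normal <- simulate_nuclei(30, m = 12L, dor = 0.28, prefix = "norm")
  dor <- estimate_dropout_rate(normal)
  har <- estimate_har(normal)
  loh <- simulate_nuclei(200, m = 10L, depth = 40L, loh = TRUE,
                         prefix = "loh")
  res <- classify_loh_events(loh, dor, har)
  expect_gte(mean(res$status == "LOH"), 0.95)
})

test_that("cell typing follows somatic marker status", {
  md <- data.frame(nucleus = c("a", "a", "b", "c"),
                   position = c(1, 2, 1, 1),
                   ref_count = c(20L, 25L, 30L, 4L),
                   alt_count = c(10L, 0L, 0L, 1L))
  ct <- assign_cell_types(md)
  expect_equal(ct$cell_type[ct$nucleus == "a"], "tumor")
  expect_equal(ct$cell_type[ct$nucleus == "b"], "normal")
  expect_equal(ct$cell_type[ct$nucleus == "c"], "unknown")
})
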