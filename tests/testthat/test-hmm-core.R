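test_that("forward-backward matches exhaustive enumeration on toy chains", {
  set.seed(101)
  for (i in 1:60) {
    T_len <- sample(2:8, 1)
    K <- sample(2:4, 1)
    chain <- random_toy_chain(T_len, K)
    fb <- hmm_forward_backward(chain$loge, chain$P, chain$init)
    enum <- enumerate_paths(chain)
    expect_equal(fb$loglik, log(sum(exp(enum$logprob))), tolerance = 1e-10)
    # marginal posteriors from enumeration
    w <- exp(enum$logprob - max(enum$logprob))
    w <- w / sum(w)
    for (t in seq_len(T_len)) {
      marg <- vapply(seq_len(K), function(k)
        sum(w[enum$paths[, t] == k]), 0)
      expect_equal(unname(fb$gamma[t, ]), marg, tolerance = 1e-9)
    }
  }
})

test_that("posteriors sum to one and transition counts to T - 1", {
  set.seed(7)
  chain <- random_toy_chain(8, 4)
  fb <- hmm_forward_backward(chain$loge, chain$P, chain$init)
  expect_equal(rowSums(fb$gamma), rep(1, 8), tolerance = 1e-9)
  expect_equal(sum(fb$xi), 7, tolerance = 1e-9)
})

test_that("single-position chain posterior is init times emission", {
  chain <- random_toy_chain(1, 3)
  fb <- hmm_forward_backward(chain$loge, chain$P, chain$init)
  expected <- chain$init * exp(chain$loge[1, ])
  expect_equal(unname(fb$gamma[1, ]), expected / sum(expected))
  expect_equal(sum(fb$gamma), 1)
})

test_that("uniform emissions return the chain prior marginals", {
  K <- 3
  P <- matrix(c(.8, .1, .1, .2, .7, .1, .3, .3, .4), K, K, byrow = TRUE)
  init <- stationary_distribution(P)
  loge <- matrix(0, 6, K)
  fb <- hmm_forward_backward(loge, P, init)
  for (t in 1:6)
    expect_equal(unname(fb$gamma[t, ]), init, tolerance = 1e-8)
})

test_that("viterbi matches exhaustive argmax and bounds the likelihood", {
  set.seed(202)
  for (i in 1:60) {
    T_len <- sample(2:8, 1)
    K <- sample(2:4, 1)
    chain <- random_toy_chain(T_len, K)
    vt <- hmm_viterbi(chain$loge, chain$P, chain$init)
    enum <- enumerate_paths(chain)
    best <- which.max(enum$logprob)
    expect_equal(vt$path, unname(enum$paths[best, ]))
    expect_equal(vt$logprob, enum$logprob[best], tolerance = 1e-9)
    fb <- hmm_forward_backward(chain$loge, chain$P, chain$init)
    expect_lte(vt$logprob, fb$loglik + 1e-9)
  }
})

test_that("viterbi breaks exact ties toward the lower state index", {
  # two states, fully symmetric: every path has equal probability
  loge <- matrix(0, 4, 2)
  P <- matrix(0.5, 2, 2)
  vt <- hmm_viterbi(loge, P, c(0.5, 0.5))
  expect_equal(vt$path, rep(1L, 4))
})

test_that("emission log-likelihoods match closed-form densities", {
  panel <- build_genotype_panel()
  params <- global_params(n = 0.25, phi = 2, s = 0.2,
                          var = rep(0.04, nrow(panel)))
  dat <- data.frame(chrom = "chr1", pos = c(100, 200),
                    ref_count = c(8, 0), depth = c(10, 0),
                    logratio = c(-0.3, 0.1))
  loge <- emission_loglik(dat, params, panel,
                          trans = transition_model(outlier = FALSE),
                          genotype_penalty = 0)
  # direct oracle for one tuple: DLOH "A" state
  g <- which(panel$label == "A")
  mu <- logratio_mean(1, 0.2, 0.25, 2)
  om <- allelic_ratio_param(1, 1, 0.2, 0.25)
  expect_equal(loge[1, g],
               dnorm(-0.3, mu, 0.2, log = TRUE) +
                 dbinom(8, 10, om, log = TRUE))
  # spot-check the binomial factor alone: dbinom(8, 10, 0.8) ~ 0.3020
  expect_equal(dbinom(8, 10, 0.8), 0.30199, tolerance = 1e-4)
  # zero depth: binomial term is zero for every tuple, so differences
  # across tuples with equal variance come from the Gaussian term only
  het <- which(panel$label == "AB")
  expect_equal(loge[2, g] - loge[2, het],
               dnorm(0.1, mu, 0.2, log = TRUE) -
                 dnorm(0.1, 0, 0.2, log = TRUE))
})

test_that("transition matrix rows are stochastic and stationary is fixed", {
  tm <- transition_model()
  P <- transition_matrix(tm, 21, 3)
  expect_equal(nrow(P), 21 * 3 + 1)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
  pi0 <- stationary_distribution(P)
  expect_equal(as.numeric(pi0 %*% P), pi0, tolerance = 1e-10)
})

test_that("forward-backward over chromosomes restarts chains", {
  sim <- two_cluster_sim(snps_per_chrom = 300L, event_snps = 60L,
                         events_per_chrom = 1L, seed = 9)
  panel <- build_genotype_panel()
  params <- initialize_params(2, sim$data, panel)
  fb <- forward_backward(sim$data, params, panel)
  expect_equal(rowSums(fb$gamma), rep(1, nrow(sim$data)), tolerance = 1e-9)
  # expected transition counts sum to T minus the number of chains
  expect_equal(sum(fb$xi), nrow(sim$data) - 2, tolerance = 1e-6)
})
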