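#' @useDynLib cloneCN, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- SNP data validation -------------------------------------------------

#' Validate a per-SNP data frame
#'
#' Checks the contract of the model input: columns `chrom`, `pos`,
#' `ref_count`, `depth`, `logratio`; counts within depth; positions
#' strictly increasing within each chromosome; finite log ratios.
#'
#' @param data Data frame of per-SNP records.
#' @return The data, invisibly, or an error.
#' @export
validate_snp_data <- function(data) {
  need <- c("chrom", "pos", "ref_count", "depth", "logratio")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing SNP data columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(data$ref_count < 0 | data$ref_count > data$depth))
    stop("reference counts must satisfy 0 <= ref_count <= depth",
         call. = FALSE)
  if (any(!is.finite(data$logratio)))
    stop("non-finite log ratios present; drop them before inference",
         call. = FALSE)
  bad <- tapply(data$pos, data$chrom, function(p) any(diff(p) <= 0))
  if (any(unlist(bad)))
    stop("positions must be strictly increasing within each chromosome",
         call. = FALSE)
  invisible(data)
}

# ---- Emissions -----------------------------------------------------------

# Per-tuple emission parameters: G x Z matrices of means and reference
# fractions, plus per-genotype sd.
tuple_emission_params <- function(panel, params) {
  G <- nrow(panel)
  Z <- length(params$s)
  mu <- om <- matrix(0, G, Z)
  for (z in seq_len(Z)) {
    mu[, z] <- logratio_mean(panel$copy_number, params$s[z], params$n,
                             params$phi)
    om[, z] <- allelic_ratio_param(panel$copy_number, panel$ref_copies,
                                   params$s[z], params$n)
  }
  list(mu = mu, omega = om, sd = sqrt(params$var))
}

#' Per-position emission log-likelihoods over the tuple space
#'
#' For tuple (g, z): Gaussian log density of the depth log ratio at mean
#' `mu_{g,z}` with the genotype's variance, plus the binomial log
#' probability of the reference count at success parameter `omega_{g,z}`.
#' The outlier state (if enabled) is uniform over the observed log-ratio
#' range and uniform over the `depth + 1` possible counts.
#'
#' @param data Validated per-SNP data frame.
#' @param params A [global_params()] object.
#' @param panel A [build_genotype_panel()] result.
#' @param trans A [transition_model()] (controls the outlier state).
#' @param l_range Log-ratio support for the outlier density; defaults to
#'   the observed range widened to at least 1 unit.
#' @param genotype_penalty Per-SNP log-prior penalty per copy of distance
#'   from the diploid state (default 0.05). Amplified genotypes form
#'   exactly degenerate pairs — a gain of one copy at prevalence q and a
#'   two-copy allele-specific amplification at q/2 imply identical
#'   (`mu`, `omega`) — and this weak parsimony prior resolves them toward
#'   the lower copy number; it is far below the per-SNP evidence
#'   separating genuinely different states.
#' @return A `nrow(data) x K` matrix of log-likelihoods, tuples in
#'   cluster-major order, outlier state last when enabled.
#' @export
emission_loglik <- function(data, params, panel = build_genotype_panel(),
                            trans = transition_model(), l_range = NULL,
                            genotype_penalty = 0.05) {
  ep <- tuple_emission_params(panel, params)
  G <- nrow(panel); Z <- length(params$s)
  K <- G * Z + as.integer(trans$outlier)
  out <- matrix(NA_real_, nrow(data), K)
  l <- data$logratio; a <- data$ref_count; N <- data$depth
  pen <- genotype_penalty * abs(panel$copy_number - 2L)
  for (z in seq_len(Z)) {
    for (g in seq_len(G)) {
      k <- tuple_index(g, z, G)
      out[, k] <- stats::dnorm(l, ep$mu[g, z], ep$sd[g], log = TRUE) +
        stats::dbinom(a, N, ep$omega[g, z], log = TRUE) - pen[g]
    }
  }
  if (trans$outlier) {
    if (is.null(l_range)) l_range <- range(l)
    span <- max(diff(l_range), 1)
    out[, K] <- -log(span) - log(N + 1)
  }
  out
}

# ---- Forward-backward / Viterbi -----------------------------------------

#' Forward–backward on a single chain (matrix interface)
#'
#' Exact scaled forward–backward recursion over one chain of emissions.
#'
#' @param loge `T x K` matrix of emission log-likelihoods.
#' @param P `K x K` row-stochastic transition matrix.
#' @param init Length-`K` initial state distribution.
#' @return List with `gamma` (`T x K` posterior marginals), `loglik`, and
#'   `xi` (`K x K` expected transition counts, summed over steps).
#' @export
hmm_forward_backward <- function(loge, P, init) {
  stopifnot(ncol(loge) == nrow(P), nrow(P) == ncol(P),
            length(init) == nrow(P))
  if (max(abs(rowSums(P) - 1)) > 1e-8)
    stop("transition matrix rows must sum to 1", call. = FALSE)
  .fwdback_core(loge, P, init / sum(init))
}

#' Viterbi decoding on a single chain (matrix interface)
#'
#' @inheritParams hmm_forward_backward
#' @return List with the 1-based `path` and its joint `logprob`. Ties are
#'   broken toward the lower state index.
#' @export
hmm_viterbi <- function(loge, P, init) {
  stopifnot(ncol(loge) == nrow(P), length(init) == nrow(P))
  .viterbi_core(loge, log(pmax(P, 1e-300)), log(pmax(init / sum(init), 1e-300)))
}

# Split row indices of a SNP data frame by chromosome, in order of first
# appearance. Chains restart at chromosome boundaries.
chrom_chains <- function(data) {
  split(seq_len(nrow(data)), factor(data$chrom, levels = unique(data$chrom)))
}

#' Posterior decoding of per-SNP data under fixed parameters
#'
#' Runs forward–backward independently per chromosome (chains share the
#' global parameters but restart at chromosome boundaries) and collects
#' marginal tuple posteriors, the total log-likelihood, and summed
#' expected transition counts.
#'
#' @inheritParams emission_loglik
#' @return List of class `posterior_result` with `gamma`, `loglik`, `xi`
#'   and `n_chains`.
#' @export
forward_backward <- function(data, params, panel = build_genotype_panel(),
                             trans = transition_model()) {
  validate_snp_data(data)
  P <- transition_matrix(trans, nrow(panel), length(params$s))
  init <- stationary_distribution(P)
  l_range <- range(data$logratio)
  chains <- chrom_chains(data)
  gamma <- matrix(NA_real_, nrow(data), nrow(P))
  xi <- matrix(0, nrow(P), nrow(P))
  ll <- 0
  for (idx in chains) {
    if (!length(idx)) next
    loge <- emission_loglik(data[idx, , drop = FALSE], params, panel, trans,
                            l_range)
    fb <- .fwdback_core(loge, P, init)
    gamma[idx, ] <- fb$gamma
    xi <- xi + fb$xi
    ll <- ll + fb$loglik
  }
  structure(list(gamma = gamma, loglik = ll, xi = xi,
                 n_chains = length(chains)),
            class = "posterior_result")
}

#' Most probable joint (genotype, cluster) path
#'
#' Viterbi decoding per chromosome under fixed parameters.
#'
#' @inheritParams emission_loglik
#' @return Data frame with one row per SNP: `tuple`, `genotype` (panel row
#'   index), `cluster`, and logical `outlier`; total path log-probability
#'   in attribute `logprob`.
#' @export
viterbi <- function(data, params, panel = build_genotype_panel(),
                    trans = transition_model()) {
  validate_snp_data(data)
  G <- nrow(panel)
  P <- transition_matrix(trans, G, length(params$s))
  lP <- log(pmax(P, 1e-300))
  linit <- log(pmax(stationary_distribution(P), 1e-300))
  l_range <- range(data$logratio)
  K_out <- if (trans$outlier) nrow(P) else 0L
  path <- integer(nrow(data))
  lp <- 0
  for (idx in chrom_chains(data)) {
    if (!length(idx)) next
    loge <- emission_loglik(data[idx, , drop = FALSE], params, panel, trans,
                            l_range)
    vt <- .viterbi_core(loge, lP, linit)
    path[idx] <- vt$path
    lp <- lp + vt$logprob
  }
  outlier <- path == K_out
  res <- data.frame(tuple = path,
                    genotype = ifelse(outlier, NA_integer_,
                                      tuple_genotype(path, G)),
                    cluster = ifelse(outlier, NA_integer_,
                                     tuple_cluster(path, G)))
  res$outlier <- outlier
  attr(res, "logprob") <- lp
  res
}

# ---- Priors and initialization ------------------------------------------

#' Weakly informative priors for the MAP M-step
#'
#' Beta(2, 2) on the normal proportion and on each cluster's `s_z`;
#' Gaussian prior on ploidy truncated to `[phi_min, phi_max]`; an
#' inverse-gamma-style shrinkage on the per-genotype variances whose scale
#' is anchored at the empirical log-ratio variance when fitting starts.
#'
#' @param n_shape,s_shape Beta shape pairs.
#' @param phi_mean,phi_sd,phi_min,phi_max Ploidy prior.
#' @param var_alpha Inverse-gamma shape for the variance shrinkage.
#' @return A list of class `cn_priors`.
#' @export
default_priors <- function(n_shape = c(2, 2), s_shape = c(2, 2),
                           phi_mean = 2, phi_sd = 0.5,
                           phi_min = 1, phi_max = 8, var_alpha = 3) {
  structure(list(n_shape = n_shape, s_shape = s_shape, phi_mean = phi_mean,
                 phi_sd = phi_sd, phi_min = phi_min, phi_max = phi_max,
                 var_alpha = var_alpha, var_beta = NULL),
            class = "cn_priors")
}

# Bound used to keep proportions off the boundary of the Beta support.
.PROP_EPS <- 1e-3

log_prior <- function(params, priors) {
  n <- min(max(params$n, .PROP_EPS), 1 - .PROP_EPS)
  s <- pmin(pmax(params$s, .PROP_EPS), 1 - .PROP_EPS)
  lp <- stats::dbeta(n, priors$n_shape[1], priors$n_shape[2], log = TRUE) +
    sum(stats::dbeta(s, priors$s_shape[1], priors$s_shape[2], log = TRUE)) +
    stats::dnorm(params$phi, priors$phi_mean, priors$phi_sd, log = TRUE)
  if (!is.null(priors$var_beta)) {
    a <- priors$var_alpha; b <- priors$var_beta
    lp <- lp + sum(-(a + 1) * log(params$var) - b / params$var)
  }
  lp
}

#' Moment-based pre-estimate of the normal proportion
#'
#' The initialization of EM benefits from a purity estimate on the right
#' scale: the even prevalence grid then spans the range of sample
#' prevalences actually present. For a hemizygous or copy-neutral LOH
#' region at sample prevalence q the expected symmetric allelic ratio is
#' `1/(2 - q)`, so `q = 2 - 1/ratio`. This estimator smooths the
#' symmetric ratio with a running median (so isolated noisy SNPs do not
#' register), keeps clearly imbalanced stretches, and takes the upper
#' quantile of the implied q as the prevalence of the most aberrant —
#' presumed clonal — events, giving `n0 = 1 - q`.
#'
#' @param data Per-SNP data frame.
#' @param window Running-median window in SNPs (odd; default 51).
#' @param min_ratio Smoothed symmetric ratio above which a stretch counts
#'   as imbalanced (default 0.55).
#' @param q_quantile Quantile of implied prevalences taken as clonal
#'   (default 0.95).
#' @param min_snps Minimum imbalanced SNPs required; otherwise 0.5 is
#'   returned (default 100).
#' @return Estimated normal proportion in \[0.05, 0.95\].
#' @export
estimate_normal_prop <- function(data, window = 51L, min_ratio = 0.55,
                                 q_quantile = 0.95, min_snps = 100L) {
  sym <- symmetric_ratio(data$ref_count, data$depth)
  sym[!is.finite(sym)] <- 0.5
  sm <- unlist(lapply(chrom_chains(data), function(idx) {
    x <- sym[idx]
    if (length(x) >= window) stats::runmed(x, window) else x
  }), use.names = FALSE)
  q <- 2 - 1 / sm[sm >= min_ratio]
  q <- q[q > 0.05]
  if (length(q) < min_snps) return(0.5)
  n0 <- 1 - as.numeric(stats::quantile(q, q_quantile))
  min(max(n0, 0.05), 0.95)
}

#' Deterministic parameter initialization
#'
#' Starting point for EM: normal proportion 0.5 (unless supplied), ploidy
#' 2, tumor prevalences evenly spaced over (0, 1\] (three clusters start at
#' 1, 2/3, 1/3), and per-genotype variances set to the empirical log-ratio
#' variance.
#'
#' @param num_clusters Number of clonal clusters (>= 1).
#' @param data Per-SNP data frame (used for the empirical variance).
#' @param panel Genotype panel.
#' @param n0,phi0 Starting normal proportion and ploidy.
#' @param seed Optional seed; the initialization is deterministic and the
#'   seed only pins downstream reproducibility bookkeeping.
#' @return A [global_params()] object.
#' @export
initialize_params <- function(num_clusters, data,
                              panel = build_genotype_panel(),
                              n0 = 0.5, phi0 = 2, seed = NULL) {
  stopifnot(num_clusters >= 1)
  if (!is.null(seed)) set.seed(seed)
  prev <- (num_clusters:1) / num_clusters
  s0 <- pmin(pmax(1 - prev, .PROP_EPS), 1 - .PROP_EPS)
  v0 <- max(stats::var(data$logratio), 1e-4)
  global_params(n = n0, phi = phi0, s = s0, var = rep(v0, nrow(panel)))
}

# ---- EM ------------------------------------------------------------------

# Expected complete-data emission log-likelihood from per-tuple sufficient
# statistics (W = posterior mass, S1/S2 = weighted first/second moments of
# l, A/M = weighted reference counts and depths), as a function of the
# parameters. Binomial combinatorial constants are omitted (parameter-free).
expected_emission_ll <- function(n, s, phi, v, panel, stats) {
  G <- nrow(panel); Z <- length(s)
  ep <- tuple_emission_params(panel, list(n = n, phi = phi, s = s, var = v))
  mu <- as.vector(ep$mu); om <- as.vector(ep$omega)
  vg <- rep(v, Z)
  gauss <- -0.5 * stats$W * log(2 * pi * vg) -
    0.5 * (stats$S2 - 2 * mu * stats$S1 + mu^2 * stats$W) / vg
  binom <- stats$A * log(om) + (stats$M - stats$A) * log1p(-om)
  sum(gauss) + sum(binom)
}

estep_stats <- function(gamma, data, n_tuple) {
  g <- gamma[, seq_len(n_tuple), drop = FALSE]
  l <- data$logratio
  mom <- crossprod(g, cbind(l, l * l, data$ref_count, data$depth))
  list(W = colSums(g), S1 = mom[, 1], S2 = mom[, 2],
       A = mom[, 3], M = mom[, 4])
}

mstep <- function(params, priors, panel, stats, sweeps = 2L) {
  n <- params$n; s <- params$s; phi <- params$phi; v <- params$var
  G <- nrow(panel); Z <- length(s)
  obj <- function(n, s, phi, v) {
    expected_emission_ll(n, s, phi, v, panel, stats) +
      log_prior(list(n = n, s = s, phi = phi, var = v), priors)
  }
  for (sweep in seq_len(sweeps)) {
    # variance: closed-form inverse-gamma MAP given current means
    ep <- tuple_emission_params(panel, list(n = n, phi = phi, s = s, var = v))
    mu <- as.vector(ep$mu)
    sse_t <- stats$S2 - 2 * mu * stats$S1 + mu^2 * stats$W
    gidx <- rep(seq_len(G), Z)
    sse_g <- tapply(sse_t, gidx, sum)
    w_g <- tapply(stats$W, gidx, sum)
    a <- priors$var_alpha; b <- priors$var_beta %||% 0
    v <- pmax(as.numeric((sse_g + 2 * b) / (w_g + 2 * (a + 1))), 1e-5)
    # bounded 1-D coordinate updates (emissions are nonlinear in n, s, phi)
    cur <- obj(n, s, phi, v)
    opt <- stats::optimize(function(x) obj(x, s, phi, v),
                           c(.PROP_EPS, 1 - .PROP_EPS), maximum = TRUE,
                           tol = 1e-5)
    if (opt$objective > cur) { n <- opt$maximum; cur <- opt$objective }
    for (z in seq_len(Z)) {
      opt <- stats::optimize(function(x) {
        sz <- s; sz[z] <- x; obj(n, sz, phi, v)
      }, c(.PROP_EPS, 1 - .PROP_EPS), maximum = TRUE, tol = 1e-5)
      if (opt$objective > cur) { s[z] <- opt$maximum; cur <- opt$objective }
    }
    opt <- stats::optimize(function(x) obj(n, s, x, v),
                           c(priors$phi_min, priors$phi_max), maximum = TRUE,
                           tol = 1e-5)
    if (opt$objective > cur) { phi <- opt$maximum; cur <- opt$objective }
  }
  global_params(n = n, phi = phi, s = s, var = v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the factorial HMM by MAP expectation maximization
#'
#' Alternates exact forward–backward E-steps (per chromosome) with MAP
#' M-steps that maximize the expected complete-data log-posterior over the
#' normal proportion, per-cluster `s_z`, ploidy and per-genotype variances
#' by bounded one-dimensional coordinate updates. Stops when the relative
#' change in log-posterior falls below `tol` or after `max_iter`
#' iterations (the latter sets `converged = FALSE` with a warning, never
#' an error). Clusters in the returned fit are sorted by decreasing tumor
#' cellular prevalence; the Viterbi decode under the final parameters is
#' included.
#'
#' @param data Validated per-SNP data frame.
#' @param num_clusters Number of clonal clusters Z (>= 1).
#' @param panel Genotype panel.
#' @param priors [default_priors()] list.
#' @param trans [transition_model()].
#' @param init Optional [global_params()] starting point; defaults to
#'   [initialize_params()].
#' @param max_iter,tol EM budget and relative log-posterior tolerance.
#' @param verbose Print per-iteration log-posteriors.
#' @return A list of class `cn_fit`: fitted `params`, cluster summary
#'   table, `loglik`, `log_posterior`, iteration `trace`, `converged`,
#'   `iterations`, per-SNP `path` (Viterbi decode with outlier flags) and
#'   `outlier_posterior`.
#' @examples
#' cfg <- sim_config(chrom_snps = c(chr1 = 600), coverage = 30,
#'                   normal_prop = 0.3, cluster_prevalences = 0.8,
#'                   events = data.frame(chrom = "chr1", start_snp = 200,
#'                                       n_snps = 200, genotype = "A",
#'                                       cluster = 1), seed = 7)
#' sim <- simulate_dataset(cfg)
#' fit <- em_fit(sim$data, num_clusters = 1, max_iter = 5)
#' fit$params$n
#' @export
em_fit <- function(data, num_clusters, panel = build_genotype_panel(),
                   priors = default_priors(), trans = transition_model(),
                   init = NULL, max_iter = 20L, tol = 1e-4,
                   verbose = FALSE) {
  stopifnot(num_clusters >= 1, nrow(data) >= 1)
  validate_snp_data(data)
  params <- init %||% initialize_params(num_clusters, data, panel,
                                        n0 = estimate_normal_prop(data))
  if (length(params$s) != num_clusters)
    stop("initial parameters disagree with 'num_clusters'", call. = FALSE)
  if (is.null(priors$var_beta))
    priors$var_beta <- (priors$var_alpha + 1) * max(stats::var(data$logratio),
                                                    1e-4)
  G <- nrow(panel)
  n_tuple <- G * num_clusters
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fb <- forward_backward(data, params, panel, trans)
    lp <- fb$loglik + log_prior(params, priors)
    trace <- c(trace, lp)
    if (verbose)
      message(sprintf("EM iter %d: log-posterior %.4f", iter, lp))
    if (iter > 1L &&
        abs(lp - trace[iter - 1L]) < tol * abs(trace[iter - 1L])) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    st <- estep_stats(fb$gamma, data, n_tuple)
    params <- mstep(params, priors, panel, st)
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations",
            call. = FALSE)
  # report clusters by decreasing tumor prevalence (increasing s_z)
  ord <- order(params$s)
  params$s <- params$s[ord]
  outlier_post <- if (trans$outlier) fb$gamma[, n_tuple + 1L] else
    rep(0, nrow(data))
  path <- viterbi(data, params, panel, trans)
  path$outlier <- path$outlier | outlier_post > 0.5
  structure(list(params = params, num_clusters = num_clusters,
                 clusters = clonal_clusters(params$s, params$n),
                 loglik = fb$loglik, log_posterior = trace[length(trace)],
                 trace = trace, iterations = iter, converged = converged,
                 path = path, outlier_posterior = outlier_post,
                 panel = panel, trans = trans, priors = priors,
                 n_snps = nrow(data)),
            class = "cn_fit")
}

#' @export
print.cn_fit <- function(x, ...) {
  cat(sprintf("HMM fit: %d SNPs, %d cluster(s), %d EM iteration(s)%s\n",
              x$n_snps, x$num_clusters, x$iterations,
              if (x$converged) "" else " (not converged)"))
  cat(sprintf("  log-posterior %.2f | n = %.3f, phi = %.3f\n",
              x$log_posterior, x$params$n, x$params$phi))
  print(x$clusters)
  invisible(x)
}
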