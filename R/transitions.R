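#' Factorised transition model for the two-chain HMM
#'
#' Both hidden chains are position-independent sticky chains. The genotype
#' chain stays in place with probability `1 - 1/expected_len_g` per SNP
#' step, spreading the remaining mass uniformly over the other genotypes;
#' the cluster chain likewise with `expected_len_z`. The joint transition
#' over (genotype, cluster) tuples is the product of the two, so a cluster
#' switch without a genotype switch is doubly penalised: prevalence changes
#' are expected to accompany event boundaries. An optional outlier state
#' absorbs isolated aberrant observations.
#'
#' @param expected_len_g Expected genotype segment length in SNP steps
#'   (default 1e6).
#' @param expected_len_z Expected cluster segment length in SNP steps
#'   (default 1e5).
#' @param outlier Include an outlier state (default TRUE).
#' @param outlier_prob Per-step probability of entering the outlier state
#'   (default 1e-3).
#' @param outlier_self Self-transition probability of the outlier state
#'   (default 0.1; outliers are expected to be isolated positions).
#' @return A list of class `transition_model`.
#' @export
transition_model <- function(expected_len_g = 1e6, expected_len_z = 1e5,
                             outlier = TRUE, outlier_prob = 1e-3,
                             outlier_self = 0.1) {
  stopifnot(expected_len_g > 1, expected_len_z > 1,
            outlier_prob >= 0, outlier_prob < 1,
            outlier_self >= 0, outlier_self < 1)
  structure(list(rho_g = 1 - 1 / expected_len_g,
                 rho_z = 1 - 1 / expected_len_z,
                 outlier = isTRUE(outlier),
                 outlier_prob = outlier_prob,
                 outlier_self = outlier_self),
            class = "transition_model")
}

# Single-chain sticky transition matrix: diag rho, off-diagonal uniform.
sticky_matrix <- function(k, rho) {
  if (k == 1L) return(matrix(1, 1, 1))
  m <- matrix((1 - rho) / (k - 1), k, k)
  diag(m) <- rho
  m
}

#' Joint tuple-space transition matrix
#'
#' Builds the row-stochastic transition matrix over the `n_geno * n_clust`
#' state tuples (cluster-major blocks), appending the outlier state if the
#' model enables it.
#'
#' @param trans A [transition_model()].
#' @param n_geno Number of genotype states.
#' @param n_clust Number of clonal clusters.
#' @return A square row-stochastic matrix.
#' @export
transition_matrix <- function(trans, n_geno, n_clust) {
  joint <- kronecker(sticky_matrix(n_clust, trans$rho_z),
                     sticky_matrix(n_geno, trans$rho_g))
  if (!trans$outlier) return(joint)
  k0 <- nrow(joint)
  p <- trans$outlier_prob
  full <- rbind(cbind(joint * (1 - p), rep(p, k0)),
                c(rep((1 - trans$outlier_self) / k0, k0), trans$outlier_self))
  full
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector with eigenvalue 1, found by power iteration; used as
#' the initial state distribution of every chromosome chain.
#'
#' @param P Row-stochastic matrix.
#' @param iter Number of power iterations (default 200).
#' @return Probability vector.
#' @export
stationary_distribution <- function(P, iter = 200L) {
  v <- rep(1 / nrow(P), nrow(P))
  tP <- t(P)
  for (i in seq_len(iter)) v <- as.numeric(tP %*% v)
  v / sum(v)
}

# Tuple index bookkeeping: tuple k = (z - 1) * n_geno + g, outlier last.
tuple_index <- function(g, z, n_geno) (z - 1L) * n_geno + g
tuple_genotype <- function(k, n_geno) (k - 1L) %% n_geno + 1L
tuple_cluster <- function(k, n_geno) (k - 1L) %/% n_geno + 1L
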