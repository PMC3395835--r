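#' Fusion configuration for Gaussian cluster-knowledge augmentation
#'
#' An input feature vector is blended with surrogate "knowledge" signals
#' sampled from the Gaussian statistics of its best-matching cluster, at a
#' significance ratio A:B (weight on the original versus the surrogate).
#'
#' @param A Weight on the original signal (default 0.8).
#' @param B Weight on the knowledge signal (default 0.2).
#' @param n_gck Number of knowledge signals generated per input (default
#'   5: sensitivity gains saturate there while specificity degrades
#'   beyond it).
#' @param seed Integer seed for the Gaussian draws.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(A = 0.8, B = 0.2, n_gck = 5, seed = 1L) {
  stopifnot(A >= 0, B >= 0, n_gck >= 0)
  if (A + B <= 0) abort("A + B must be positive")
  structure(list(A = A, B = B, n_gck = as.integer(n_gck),
                 seed = as.integer(seed)),
            class = "fusion_config")
}

# Scalar kernel scale per cluster: root-mean-square of the per-dimension
# sigma components.
cluster_scales <- function(model) {
  sqrt(rowMeans(model$sigma^2))
}

#' Cluster membership of a feature vector
#'
#' Rate of membership of `gamma` in each cluster through a Gaussian radial
#' basis kernel: theta_i = exp(-||gamma - mu_i||^2 / (2 s_i^2)), where s_i
#' is the RMS of cluster i's per-dimension standard deviations. Membership
#' is 1 exactly at a centroid and decays monotonically with distance. A
#' zero-scale cluster gives membership 1 at its centroid and 0 elsewhere.
#'
#' @param gamma Numeric feature vector.
#' @param model A `regpso_fit`.
#' @return Numeric vector of memberships in (0, 1] (or exactly 0 for a
#'   degenerate zero-scale cluster away from its centroid).
#' @export
gck_membership <- function(gamma, model) {
  s <- cluster_scales(model)
  d2 <- rowSums((model$mu - matrix(gamma, nrow(model$mu), ncol(model$mu),
                                   byrow = TRUE))^2)
  theta <- ifelse(s > 0, exp(-d2 / (2 * s^2)), as.numeric(d2 == 0))
  theta
}

#' Select the seed cluster for knowledge generation
#'
#' @param theta Membership vector from [gck_membership()].
#' @return 1-based index of the maximal membership; ties break toward the
#'   lowest index.
#' @export
gck_seed_cluster <- function(theta) {
  if (length(theta) == 0) abort("empty membership profile")
  which.max(theta)
}

#' Draw a Gaussian knowledge signal from a cluster
#'
#' Each component d is drawn independently from
#' Normal(mu_I\[d\], sigma_I\[d\]).
#'
#' @param model A `regpso_fit`.
#' @param cluster 1-based seed cluster index.
#' @param seed Optional integer seed.
#' @return Numeric vector, one draw of the cluster's Gaussian.
#' @export
gck_knowledge_signal <- function(model, cluster, seed = NULL) {
  stopifnot(cluster >= 1, cluster <= nrow(model$mu))
  with_seed(seed, rnorm(ncol(model$mu), model$mu[cluster, ],
                        model$sigma[cluster, ]))
}

#' Fuse an input with a knowledge signal
#'
#' Weighted blend (A * gamma + B * ybar) / (A + B); a convex combination
#' for non-negative weights.
#'
#' @param gamma Original feature vector.
#' @param ybar Knowledge signal of the same length.
#' @param cfg A [fusion_config()] (only `A` and `B` are used).
#' @return Fused numeric vector.
#' @export
gck_fuse <- function(gamma, ybar, cfg = fusion_config()) {
  stopifnot(length(gamma) == length(ybar))
  (cfg$A * gamma + cfg$B * ybar) / (cfg$A + cfg$B)
}

#' Generate a batch of fused cluster-knowledge signals
#'
#' Finds the best-matching cluster of `gamma`, draws `cfg$n_gck`
#' independent knowledge signals from it, and fuses each with `gamma`.
#'
#' @param gamma Feature vector.
#' @param model A `regpso_fit`.
#' @param cfg A [fusion_config()].
#' @param seed Integer seed; defaults to the fusion config's seed.
#' @return Matrix with `n_gck` rows (possibly 0), each a fused signal.
#' @export
gck_batch <- function(gamma, model, cfg = fusion_config(), seed = cfg$seed) {
  n <- cfg$n_gck
  if (n == 0) return(matrix(numeric(0), 0, length(gamma)))
  I <- gck_seed_cluster(gck_membership(gamma, model))
  with_seed(seed, {
    out <- matrix(0, n, length(gamma))
    for (k in seq_len(n)) {
      ybar <- rnorm(ncol(model$mu), model$mu[I, ], model$sigma[I, ])
      out[k, ] <- gck_fuse(gamma, ybar, cfg)
    }
    out
  })
}
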