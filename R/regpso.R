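#' Configuration for regrouping particle swarm clustering
#'
#' Global-best PSO explores candidate centroid placements; when the swarm
#' collapses onto its global best (premature convergence), particles are
#' re-scattered in a regrouping box around the best position and the search
#' continues. Defaults follow the standard constricted-PSO constants.
#'
#' @param n_clusters Number of clusters Nc.
#' @param swarm_size Number of particles.
#' @param inertia Velocity inertia weight.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param stagnation_eps Normalized swarm radius below which a regroup is
#'   triggered.
#' @param max_iters Total PSO iterations across all regroup episodes.
#' @param max_regroups Maximum number of regroup episodes.
#' @param seed Integer seed for reproducibility.
#' @return A list of class `regpso_config`.
#' @export
regpso_config <- function(n_clusters = 8, swarm_size = 20, inertia = 0.72,
                          c1 = 1.49, c2 = 1.49, stagnation_eps = 1.1e-4,
                          max_iters = 250, max_regroups = 4, seed = 1L) {
  stopifnot(swarm_size >= 2, n_clusters >= 1, stagnation_eps > 0,
            max_iters >= 1, max_regroups >= 0)
  structure(
    list(n_clusters = n_clusters, swarm_size = swarm_size, inertia = inertia,
         c1 = c1, c2 = c2, stagnation_eps = stagnation_eps,
         max_iters = max_iters, max_regroups = max_regroups,
         seed = as.integer(seed)),
    class = "regpso_config"
  )
}

decode_centroids <- function(position, n_clusters) {
  matrix(position, nrow = n_clusters, byrow = TRUE)
}

# Squared Euclidean distances between rows of x (n x d) and rows of c
# (k x d); returns n x k.
cross_dist2 <- function(x, cent) {
  d2 <- outer(rowSums(x^2), rowSums(cent^2), "+") - 2 * x %*% t(cent)
  d2[d2 < 0] <- 0
  d2
}

#' Quantization error of a centroid placement
#'
#' Mean over non-empty clusters of the mean Euclidean distance from each
#' member to its nearest centroid — the standard PSO-clustering objective.
#'
#' @param position Numeric vector: Nc centroids concatenated row-wise.
#' @param data Numeric matrix or data frame of observations (rows).
#' @param n_clusters Number of clusters encoded in `position`.
#' @return Non-negative scalar fitness (lower is better).
#' @export
quantization_fitness <- function(position, data, n_clusters) {
  if (n_clusters < 1) abort("n_clusters must be >= 1")
  x <- as_feature_matrix(data)
  cent <- decode_centroids(position, n_clusters)
  d <- sqrt(cross_dist2(x, cent))
  idx <- max.col(-d, ties.method = "first")
  nearest <- d[cbind(seq_len(nrow(x)), idx)]
  per <- tapply(nearest, factor(idx, levels = seq_len(n_clusters)), mean)
  mean(per[!is.na(per)])
}

new_swarm <- function(data, cfg) {
  d <- ncol(data)
  nd <- cfg$n_clusters * d
  lo <- apply(data, 2, min)
  hi <- apply(data, 2, max)
  lo_full <- rep(lo, times = cfg$n_clusters)
  hi_full <- rep(hi, times = cfg$n_clusters)
  # seed each particle's centroids at randomly drawn observations, the
  # usual PSO-clustering initialization
  x <- t(vapply(seq_len(cfg$swarm_size), function(i) {
    idx <- sample(nrow(data), cfg$n_clusters,
                  replace = nrow(data) < cfg$n_clusters)
    as.vector(t(data[idx, , drop = FALSE]))
  }, numeric(nd)))
  fit <- apply(x, 1, quantization_fitness, data = data,
               n_clusters = cfg$n_clusters)
  gi <- which.min(fit)
  list(x = x, v = matrix(0, cfg$swarm_size, nd), p = x, p_fitness = fit,
       g = x[gi, ], g_fitness = fit[gi], iteration = 0L, regroup_count = 0L,
       lo = lo_full, hi = hi_full, trace = fit[gi])
}

#' One global-best PSO iteration
#'
#' Updates each particle's velocity with inertia, cognitive (toward its
#' personal best) and social (toward the global best) terms under uniform
#' random scaling, moves the particle, clamps it to the search box, and
#' refreshes personal/global bests. The global best fitness never
#' increases.
#'
#' @param state Swarm state from `new_swarm()` or a previous step.
#' @param data Numeric observation matrix.
#' @param cfg A [regpso_config()].
#' @return Updated swarm state.
#' @export
pso_step <- function(state, data, cfg) {
  ns <- cfg$swarm_size
  nd <- length(state$g)
  r1 <- matrix(runif(ns * nd), ns)
  r2 <- matrix(runif(ns * nd), ns)
  g_mat <- matrix(state$g, ns, nd, byrow = TRUE)
  state$v <- cfg$inertia * state$v +
    cfg$c1 * r1 * (state$p - state$x) +
    cfg$c2 * r2 * (g_mat - state$x)
  vmax <- state$hi - state$lo
  state$v <- pmin(pmax(state$v, matrix(-vmax, ns, nd, byrow = TRUE)),
                  matrix(vmax, ns, nd, byrow = TRUE))
  state$x <- state$x + state$v
  state$x <- pmin(pmax(state$x, matrix(state$lo, ns, nd, byrow = TRUE)),
                  matrix(state$hi, ns, nd, byrow = TRUE))
  fit <- apply(state$x, 1, quantization_fitness, data = data,
               n_clusters = cfg$n_clusters)
  better <- fit < state$p_fitness
  state$p[better, ] <- state$x[better, , drop = FALSE]
  state$p_fitness[better] <- fit[better]
  gi <- which.min(state$p_fitness)
  if (state$p_fitness[gi] < state$g_fitness) {
    state$g <- state$p[gi, ]
    state$g_fitness <- state$p_fitness[gi]
  }
  state$iteration <- state$iteration + 1L
  state$trace <- c(state$trace, state$g_fitness)
  state
}

#' Detect swarm collapse and regroup
#'
#' When the maximum particle distance to the global best, normalized by the
#' search-space diameter, falls below `stagnation_eps`, particles are
#' re-scattered uniformly in a box centered on the global best. The box's
#' per-dimension extent is the swarm's per-dimension deviation from the
#' best, inflated by the regrouping factor 6/(5 eps) and capped at the
#' original search range. The global best (and its fitness) is preserved.
#'
#' @param state Swarm state.
#' @param cfg A [regpso_config()].
#' @return Possibly regrouped swarm state.
#' @export
check_and_regroup <- function(state, cfg) {
  diam <- sqrt(sum((state$hi - state$lo)^2))
  if (diam == 0) return(state)
  dists <- sqrt(rowSums((state$x - matrix(state$g, nrow(state$x),
                                          ncol(state$x), byrow = TRUE))^2))
  if (max(dists) / diam >= cfg$stagnation_eps) return(state)
  rho <- 6 / (5 * cfg$stagnation_eps)
  dev <- apply(abs(state$x - matrix(state$g, nrow(state$x), ncol(state$x),
                                    byrow = TRUE)), 2, max)
  # floor the deviation so a fully collapsed swarm still re-scatters
  dev <- pmax(dev, cfg$stagnation_eps * (state$hi - state$lo))
  extent <- pmin(state$hi - state$lo, rho * dev)
  ns <- nrow(state$x)
  nd <- ncol(state$x)
  u <- matrix(runif(ns * nd, -0.5, 0.5), ns)
  state$x <- matrix(state$g, ns, nd, byrow = TRUE) +
    u * matrix(extent, ns, nd, byrow = TRUE)
  state$x <- pmin(pmax(state$x, matrix(state$lo, ns, nd, byrow = TRUE)),
                  matrix(state$hi, ns, nd, byrow = TRUE))
  state$v <- matrix(0, ns, nd)
  state$regroup_count <- state$regroup_count + 1L
  state
}

#' Cluster feature vectors with regrouping particle swarm optimization
#'
#' Runs gbest PSO over concatenated centroid positions with regroup
#' episodes on stagnation, then assigns every observation to its nearest
#' centroid and summarizes each cluster by its member mean and
#' per-dimension standard deviation — the Gaussian statistics later used by
#' the radial basis layer and the cluster-knowledge augmentation.
#'
#' @param data Data frame (feature columns `f*` or all-numeric) or numeric
#'   matrix; rows are observations.
#' @param cfg A [regpso_config()].
#' @return An object of class `regpso_fit` with elements `mu` (Nc x d
#'   centroid matrix), `sigma` (Nc x d population SDs), `counts`, `fitness`
#'   (final quantization error), `trace` (best fitness per iteration),
#'   `regroups`, and the configuration.
#' @export
cluster_regpso <- function(data, cfg = regpso_config()) {
  x <- as_feature_matrix(if (is.data.frame(data) &&
                             length(feature_cols(data)) > 0)
    data[, feature_cols(data)] else data)
  if (nrow(x) < cfg$n_clusters) {
    abort("need at least as many observations as clusters")
  }
  with_seed(cfg$seed, {
    state <- new_swarm(x, cfg)
    while (state$iteration < cfg$max_iters) {
      state <- pso_step(state, x, cfg)
      if (state$regroup_count < cfg$max_regroups) {
        state <- check_and_regroup(state, cfg)
      }
    }
    finalize_cluster_model(state, x, cfg)
  })
}

finalize_cluster_model <- function(state, x, cfg) {
  k <- cfg$n_clusters
  mu0 <- decode_centroids(state$g, k)
  d <- sqrt(cross_dist2(x, mu0))
  idx <- max.col(-d, ties.method = "first")
  counts <- tabulate(idx, nbins = k)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  global_sd <- apply(x, 2, pop_sd)
  mu <- mu0
  sigma <- matrix(0, k, ncol(x))
  for (i in seq_len(k)) {
    if (counts[i] > 0) {
      xi <- x[idx == i, , drop = FALSE]
      mu[i, ] <- colMeans(xi)
      sigma[i, ] <- apply(xi, 2, pop_sd)
    } else {
      sigma[i, ] <- global_sd
      warn(sprintf("cluster %d is empty; keeping its centroid with the global per-dimension SD", i))
    }
  }
  structure(
    list(mu = mu, sigma = sigma, counts = counts,
         fitness = state$g_fitness, trace = state$trace,
         regroups = state$regroup_count, iterations = state$iteration,
         config = cfg, n = nrow(x)),
    class = "regpso_fit"
  )
}

#' Assign observations to their nearest cluster centroid
#'
#' @param data Numeric matrix/data frame of observations, or a single
#'   vector.
#' @param model A `regpso_fit`.
#' @return Integer vector of 1-based cluster indices; ties break toward the
#'   lowest index.
#' @export
assign_cluster <- function(data, model) {
  x <- as_feature_matrix(if (is.data.frame(data) &&
                             length(feature_cols(data)) > 0)
    data[, feature_cols(data)] else data)
  d2 <- cross_dist2(x, model$mu)
  max.col(-d2, ties.method = "first")
}

#' @export
print.regpso_fit <- function(x, ...) {
  cat(sprintf("RegPSO clustering: %d clusters over %d observations (%d dims)\n",
              nrow(x$mu), x$n, ncol(x$mu)))
  cat(sprintf("  quantization error %.5f after %d iterations, %d regroup episode(s)\n",
              x$fitness, x$iterations, x$regroups))
  cat(sprintf("  cluster sizes: %s\n", paste(x$counts, collapse = ", ")))
  invisible(x)
}
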