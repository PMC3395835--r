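# Shared fixtures, built in code at test time.

# Two-dimensional Gaussian blob features with labels, as a feature tibble.
make_blob_features <- function(n_per, centers, sd = 0.1, seed = 1) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    expr
  }
  withr_seed({
    rows <- lapply(seq_len(nrow(centers)), function(i) {
      tibble::tibble(
        f1 = rnorm(n_per, centers[i, 1], sd),
        f2 = rnorm(n_per, centers[i, 2], sd),
        label = if (i %% 2 == 1) "fall" else "adl"
      )
    })
    dplyr::bind_rows(rows)
  })
}

# A hand-built cluster model (bypassing PSO) for unit tests of the GCK and
# RBF layers.
make_cluster_model <- function(mu, sigma = NULL, counts = NULL) {
  if (is.null(sigma)) sigma <- matrix(1, nrow(mu), ncol(mu))
  if (is.null(counts)) counts <- rep(1L, nrow(mu))
  structure(list(mu = mu, sigma = sigma, counts = counts,
                 fitness = NA_real_, trace = NA_real_, regroups = 0L,
                 iterations = 0L, config = regpso_config(n_clusters = nrow(mu)),
                 n = sum(counts)),
            class = "regpso_fit")
}

# A constant-gravity raw window (orientation (0, 0, 1) g) at 20 Hz.
make_quiet_window <- function(n = 100, hz = 20) {
  t <- seq(-n / (2 * hz), by = 1 / hz, length.out = n)
  w <- tibble::tibble(time_s = t, ax_g = 0, ay_g = 0, az_g = 1)
  attr(w, "tau") <- 0
  attr(w, "sampling_hz") <- hz
  class(w) <- c("accel_window", class(w))
  w
}

# Brute-force nearest-centroid quantization error: independent of the
# package's vectorized implementation.
brute_quantization <- function(position, x, k) {
  cent <- matrix(position, nrow = k, byrow = TRUE)
  nearest <- integer(nrow(x))
  dist <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    ds <- apply(cent, 1, function(m) sqrt(sum((x[i, ] - m)^2)))
    nearest[i] <- which.min(ds)
    dist[i] <- min(ds)
  }
  per <- sapply(seq_len(k), function(j) {
    if (any(nearest == j)) mean(dist[nearest == j]) else NA_real_
  })
  mean(per, na.rm = TRUE)
}

# Weiszfeld geometric median (the optimal centroid under mean Euclidean
# distance).
geometric_median <- function(X, iters = 100, tol = 1e-10) {
  y <- colMeans(X)
  for (it in seq_len(iters)) {
    d <- sqrt(rowSums(sweep(X, 2, y)^2))
    w <- 1 / pmax(d, 1e-12)
    y_new <- colSums(X * w) / sum(w)
    if (sqrt(sum((y_new - y)^2)) < tol) return(y_new)
    y <- y_new
  }
  y
}

# Global optimum of the 2-cluster quantization error by exhaustive
# bipartition enumeration with geometric-median centroids.
exhaustive_two_cluster_optimum <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    mask <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (!any(mask) || all(mask)) next
    m1 <- geometric_median(x[mask, , drop = FALSE])
    m2 <- geometric_median(x[!mask, , drop = FALSE])
    f <- quantization_fitness(c(m1, m2), x, 2)
    if (f < best) best <- f
  }
  best
}
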