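#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a RegPSO clustering fit
#'
#' Long-form cluster summary: one row per cluster and dimension with the
#' centroid coordinate and the per-dimension standard deviation.
#'
#' @param x A `regpso_fit`.
#' @param ... Unused.
#' @return A tibble with columns `cluster`, `size`, `dimension`, `mu`,
#'   `sigma`.
#' @method tidy regpso_fit
#' @export
tidy.regpso_fit <- function(x, ...) {
  k <- nrow(x$mu)
  d <- ncol(x$mu)
  tibble(cluster = rep(seq_len(k), each = d),
         size = rep(x$counts, each = d),
         dimension = rep(paste0("f", seq_len(d)), k),
         mu = as.vector(t(x$mu)),
         sigma = as.vector(t(x$sigma)))
}

#' @rdname tidy.regpso_fit
#' @method glance regpso_fit
#' @export
glance.regpso_fit <- function(x, ...) {
  tibble(n_clusters = nrow(x$mu), n_obs = x$n,
         fitness = x$fitness, iterations = x$iterations,
         regroups = x$regroups, n_empty = sum(x$counts == 0))
}

#' One-row summaries of trained classifiers
#'
#' @param x An `mlp_fit`, `arbf_fit` or `fall_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble of architecture and training diagnostics.
#' @method glance mlp_fit
#' @export
glance.mlp_fit <- function(x, ...) {
  tibble(hidden = x$config$hidden, epochs = x$epochs,
         best_epoch = x$best_epoch, val_mse = x$best_val)
}

#' @rdname glance.mlp_fit
#' @method glance arbf_fit
#' @export
glance.arbf_fit <- function(x, ...) {
  tibble(rbf_nodes = nrow(x$cluster_model$mu), hidden = x$config$hidden,
         epochs = x$epochs, best_epoch = x$best_epoch, val_mse = x$best_val)
}

#' @rdname glance.mlp_fit
#' @method glance fall_ensemble
#' @export
glance.fall_ensemble <- function(x, ...) {
  tibble(n_gck = x$fusion$n_gck, ratio_a = x$fusion$A, ratio_b = x$fusion$B,
         votes_per_input = 2L * (x$fusion$n_gck + 1L),
         tie_rule = x$tie_rule,
         cluster_fitness = x$cluster_model$fitness)
}
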