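#' Radial basis layer forward pass
#'
#' Each node n outputs a Gaussian kernel of the distance between the input
#' and its centroid mu_n at scale sigma_n (the RMS of the cluster's
#' per-dimension standard deviations, floored at a tiny positive value so
#' degenerate clusters respond only at their centroid). Outputs lie in
#' (0, 1], so the layer doubles as a normalizer: no further input scaling
#' is applied downstream.
#'
#' @param x Numeric matrix of inputs (rows) or a single vector.
#' @param model A `regpso_fit` supplying centroids and scales.
#' @return Matrix with one row per input and one column per RBF node.
#' @export
rbf_layer_forward <- function(x, model) {
  x <- as_feature_matrix(if (is.data.frame(x) && length(feature_cols(x)) > 0)
    x[, feature_cols(x)] else x)
  s <- pmax(cluster_scales(model), 1e-8)
  d2 <- cross_dist2(x, model$mu)
  exp(-sweep(d2, 2, 2 * s^2, "/"))
}

#' Train an augmented radial basis function classifier
#'
#' Freezes an RBF layer on the cluster centroids and standard deviations
#' found by [cluster_regpso()], passes the features through it, and trains
#' an MLP augmentation layer (Nc -> hidden -> 1) on the RBF outputs with
#' resilient backpropagation. No normalization is inserted between the two
#' stages: the kernel already maps into (0, 1].
#'
#' @param train,val Feature tibbles (`f*` columns plus `label`).
#' @param cluster_model A `regpso_fit` fitted on training-distribution
#'   features.
#' @param cfg An [rprop_config()] for the augmentation layer.
#' @return An object of class `arbf_fit` containing the frozen layer and
#'   the trained augmentation network.
#' @export
train_arbf <- function(train, val, cluster_model, cfg = rprop_config()) {
  tr <- split_xy(train)
  vl <- split_xy(val)
  if (length(unique(tr$y)) < 2) {
    abort("training set must contain both classes")
  }
  phi_tr <- rbf_layer_forward(tr$x, cluster_model)
  phi_vl <- rbf_layer_forward(vl$x, cluster_model)
  fit <- with_seed(cfg$seed,
                   train_net_rprop(phi_tr, tr$y, phi_vl, vl$y, cfg))
  structure(list(cluster_model = cluster_model, net = fit$net,
                 threshold = cfg$threshold, config = cfg,
                 best_epoch = fit$best_epoch, epochs = fit$epochs,
                 val_curve = fit$val_curve, best_val = fit$best_val),
            class = "arbf_fit")
}

#' @export
predict.arbf_fit <- function(object, newdata, type = c("label", "score"), ...) {
  type <- match.arg(type)
  phi <- rbf_layer_forward(newdata, object$cluster_model)
  score <- mlp_forward(object$net, phi)
  if (type == "score") return(score)
  ifelse(score > object$threshold, "fall", "adl")
}

#' @export
print.arbf_fit <- function(x, ...) {
  cat(sprintf("ARBF fall classifier: frozen RBF layer (%d nodes) + MLP %d -> %d -> 1\n",
              nrow(x$cluster_model$mu), nrow(x$cluster_model$mu),
              x$config$hidden))
  cat(sprintf("  Rprop, %d epochs run, best validation MSE %.4f at epoch %d\n",
              x$epochs, x$best_val, x$best_epoch))
  invisible(x)
}
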