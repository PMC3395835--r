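#' Resilient backpropagation configuration
#'
#' Constants for the sign-based Rprop weight update (the iRprop- variant:
#' on a gradient sign change the step shrinks and that gradient is zeroed).
#' Because updates depend only on gradient signs, training is invariant to
#' positive rescaling of the loss.
#'
#' @param initial_step Initial per-weight step size.
#' @param step_min,step_max Step size bounds.
#' @param eta_plus,eta_minus Step increase / decrease factors
#'   (0 < eta_minus < 1 < eta_plus).
#' @param max_epochs Maximum full-batch epochs.
#' @param patience Early-stop patience: epochs without validation
#'   improvement before training halts.
#' @param hidden Hidden layer width.
#' @param threshold Decision threshold on the linear output against
#'   targets coded fall = 1, adl = 0.
#' @param seed Integer seed for weight initialization.
#' @return A list of class `rprop_config`.
#' @export
rprop_config <- function(initial_step = 0.07, step_min = 1e-6, step_max = 50,
                         eta_plus = 1.2, eta_minus = 0.5, max_epochs = 300,
                         patience = 50, hidden = 10, threshold = 0.5,
                         seed = 1L) {
  stopifnot(eta_minus > 0, eta_minus < 1, eta_plus > 1,
            step_min > 0, step_max > step_min, max_epochs >= 0, hidden >= 1)
  structure(list(initial_step = initial_step, step_min = step_min,
                 step_max = step_max, eta_plus = eta_plus,
                 eta_minus = eta_minus, max_epochs = max_epochs,
                 patience = patience, hidden = hidden, threshold = threshold,
                 seed = as.integer(seed)),
            class = "rprop_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_forward <- function(net, x) {
  h <- sigmoid(sweep(x %*% net$W1, 2, net$b1, "+"))
  drop(h %*% net$W2 + net$b2)
}

mlp_gradients <- function(net, x, y) {
  n <- nrow(x)
  h <- sigmoid(sweep(x %*% net$W1, 2, net$b1, "+"))
  out <- drop(h %*% net$W2 + net$b2)
  e <- matrix((out - y) / n, ncol = 1)
  dh <- e %*% t(net$W2) * h * (1 - h)
  list(W1 = t(x) %*% dh, b1 = colSums(dh),
       W2 = t(h) %*% e, b2 = sum(e))
}

init_net <- function(d, hidden) {
  list(W1 = matrix(runif(d * hidden, -0.5, 0.5), d, hidden),
       b1 = runif(hidden, -0.5, 0.5),
       W2 = matrix(runif(hidden, -0.5, 0.5), hidden, 1),
       b2 = runif(1, -0.5, 0.5))
}

net_apply2 <- function(a, b, f) {
  list(W1 = f(a$W1, b$W1), b1 = f(a$b1, b$b1),
       W2 = f(a$W2, b$W2), b2 = f(a$b2, b$b2))
}

# One iRprop- update; returns updated net, steps and previous-gradient
# store.
rprop_update <- function(net, grad, step, prev, cfg) {
  for (nm in c("W1", "b1", "W2", "b2")) {
    g <- grad[[nm]]
    s <- sign(g * prev[[nm]])
    st <- step[[nm]]
    st[s > 0] <- pmin(st[s > 0] * cfg$eta_plus, cfg$step_max)
    st[s < 0] <- pmax(st[s < 0] * cfg$eta_minus, cfg$step_min)
    g[s < 0] <- 0
    net[[nm]] <- net[[nm]] - sign(g) * st
    step[[nm]] <- st
    prev[[nm]] <- g
  }
  list(net = net, step = step, prev = prev)
}

train_net_rprop <- function(x, y, x_val, y_val, cfg) {
  net <- init_net(ncol(x), cfg$hidden)
  zero <- net_apply2(net, net, function(a, b) a * 0)
  step <- net_apply2(net, net, function(a, b) a * 0 + cfg$initial_step)
  prev <- zero
  val_mse <- function(n) mean((mlp_forward(n, x_val) - y_val)^2)
  best <- net
  best_val <- val_mse(net)
  best_epoch <- 0L
  curve <- best_val
  since <- 0L
  epoch <- 0L
  while (epoch < cfg$max_epochs) {
    grad <- mlp_gradients(net, x, y)
    up <- rprop_update(net, grad, step, prev, cfg)
    net <- up$net; step <- up$step; prev <- up$prev
    epoch <- epoch + 1L
    v <- val_mse(net)
    curve <- c(curve, v)
    if (v < best_val) {
      best_val <- v; best <- net; best_epoch <- epoch; since <- 0L
    } else {
      since <- since + 1L
      if (since >= cfg$patience) break
    }
  }
  list(net = best, best_epoch = best_epoch, epochs = epoch,
       val_curve = curve, best_val = best_val)
}

split_xy <- function(df) {
  fc <- feature_cols(df)
  if (length(fc) == 0) abort("no feature columns (f1, f2, ...) found")
  list(x = as.matrix(df[, fc]),
       y = as.numeric(df$label == "fall"))
}

#' Train a multilayer perceptron fall classifier
#'
#' A 13 -> hidden -> 1 network with sigmoid hidden units and a linear
#' output, trained with full-batch resilient backpropagation against
#' targets fall = 1, adl = 0. The epoch snapshot with the best validation
#' mean squared error is returned.
#'
#' @param train,val Feature tibbles (columns `f*` plus `label`). Both
#'   classes must be present in `train`.
#' @param cfg An [rprop_config()].
#' @return An object of class `mlp_fit`.
#' @export
train_mlp <- function(train, val, cfg = rprop_config()) {
  tr <- split_xy(train)
  vl <- split_xy(val)
  if (length(unique(tr$y)) < 2) {
    abort("training set must contain both classes")
  }
  fit <- with_seed(cfg$seed, train_net_rprop(tr$x, tr$y, vl$x, vl$y, cfg))
  structure(list(net = fit$net, threshold = cfg$threshold, config = cfg,
                 best_epoch = fit$best_epoch, epochs = fit$epochs,
                 val_curve = fit$val_curve, best_val = fit$best_val,
                 d_in = ncol(tr$x)),
            class = "mlp_fit")
}

#' @export
predict.mlp_fit <- function(object, newdata, type = c("label", "score"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else as.matrix(newdata[, feature_cols(newdata)])
  score <- mlp_forward(object$net, x)
  if (type == "score") return(score)
  ifelse(score > object$threshold, "fall", "adl")
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf("MLP fall classifier: %d -> %d -> 1 (sigmoid/linear)\n",
              x$d_in, x$config$hidden))
  cat(sprintf("  Rprop, %d epochs run, best validation MSE %.4f at epoch %d\n",
              x$epochs, x$best_val, x$best_epoch))
  invisible(x)
}
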