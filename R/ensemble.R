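#' Assemble a majority-vote fall-detection ensemble
#'
#' Pairs a trained MLP and ARBF with the cluster model and fusion
#' configuration used for Gaussian cluster-knowledge augmentation at
#' prediction time.
#'
#' @param mlp An `mlp_fit`.
#' @param arbf An `arbf_fit`.
#' @param cluster_model The `regpso_fit` shared by the RBF layer and the
#'   augmentation.
#' @param fusion A [fusion_config()].
#' @param tie_rule Label returned on an exact vote tie; the default
#'   `"fall"` favors sensitivity.
#' @return An object of class `fall_ensemble`.
#' @export
fall_ensemble <- function(mlp, arbf, cluster_model,
                          fusion = fusion_config(), tie_rule = "fall") {
  stopifnot(inherits(mlp, "mlp_fit"), inherits(arbf, "arbf_fit"),
            inherits(cluster_model, "regpso_fit"),
            tie_rule %in% c("fall", "adl"))
  structure(list(mlp = mlp, arbf = arbf, cluster_model = cluster_model,
                 fusion = fusion, tie_rule = tie_rule),
            class = "fall_ensemble")
}

# Expand each input row into itself plus n_gck fused knowledge signals;
# per-row seeds derive from the fusion seed so prediction is reproducible.
expand_signals <- function(x, model, fusion) {
  n <- nrow(x)
  per <- fusion$n_gck + 1L
  out <- matrix(0, n * per, ncol(x))
  for (i in seq_len(n)) {
    gamma <- x[i, ]
    block <- (i - 1L) * per
    out[block + 1L, ] <- gamma
    if (fusion$n_gck > 0) {
      out[block + 1L + seq_len(fusion$n_gck), ] <-
        gck_batch(gamma, model, fusion, seed = derive_seed(fusion$seed, i))
    }
  }
  out
}

#' Predict with the ensemble by pooled majority vote
#'
#' Each input is expanded into itself plus `n_gck` cluster-knowledge fused
#' signals; both networks classify every signal, pooling 2 * (n_gck + 1)
#' votes per input. The majority label wins; an exact tie falls back to
#' the ensemble's tie rule.
#'
#' @param object A `fall_ensemble`.
#' @param newdata Feature tibble or matrix.
#' @param type `"label"` for labels only, `"tally"` for a tibble with the
#'   vote breakdown.
#' @param ... Unused.
#' @return Character vector of labels, or a tibble with columns `label`,
#'   `votes_fall`, `votes_adl`.
#' @export
predict.fall_ensemble <- function(object, newdata,
                                  type = c("label", "tally"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else
    as.matrix(newdata[, feature_cols(newdata)])
  per <- object$fusion$n_gck + 1L
  sig <- expand_signals(x, object$cluster_model, object$fusion)
  v_mlp <- predict(object$mlp, sig) == "fall"
  v_arbf <- predict(object$arbf, sig) == "fall"
  grp <- rep(seq_len(nrow(x)), each = per)
  votes_fall <- tapply(v_mlp, grp, sum) + tapply(v_arbf, grp, sum)
  total <- 2L * per
  votes_fall <- as.integer(votes_fall)
  label <- ifelse(votes_fall * 2L > total, "fall",
                  ifelse(votes_fall * 2L < total, "adl", object$tie_rule))
  if (type == "label") return(unname(label))
  tibble(label = unname(label), votes_fall = votes_fall,
         votes_adl = total - votes_fall)
}

#' @export
print.fall_ensemble <- function(x, ...) {
  cat(sprintf("Fall-detection ensemble: MLP + ARBF, %d GCK signals (A:B = %g:%g), %d votes per input, tie -> %s\n",
              x$fusion$n_gck, x$fusion$A, x$fusion$B,
              2L * (x$fusion$n_gck + 1L), x$tie_rule))
  invisible(x)
}

#' Sensitivity and specificity of predictions, per stratum
#'
#' Sensitivity = TP / (TP + FN) * 100 over fall windows; specificity =
#' TN / (TN + FP) * 100 over ADL windows, reported overall and broken down
#' by substratum when available. A stratum with no members is reported as
#' `NA`, not zero.
#'
#' @param data Tibble with a `label` column (`"fall"`/`"adl"`) and
#'   optionally `substratum`.
#' @param pred Character vector of predicted labels, same length.
#' @return Tibble with columns `stratum`, `metric`, `value` (percent),
#'   `n`.
#' @export
evaluate_predictions <- function(data, pred) {
  stopifnot(nrow(data) == length(pred))
  if (nrow(data) == 0) abort("cannot evaluate an empty set")
  truth <- data$label
  rate <- function(mask, target) {
    n <- sum(mask)
    v <- if (n == 0) NA_real_ else 100 * mean(pred[mask] == target)
    list(value = v, n = n)
  }
  rows <- list(
    tibble(stratum = "overall", metric = "sensitivity",
           value = rate(truth == "fall", "fall")$value,
           n = sum(truth == "fall")),
    tibble(stratum = "overall", metric = "specificity",
           value = rate(truth == "adl", "adl")$value,
           n = sum(truth == "adl"))
  )
  if ("substratum" %in% names(data)) {
    for (s in unique(data$substratum)) {
      mask <- data$substratum == s
      is_fall <- truth[mask][1] == "fall"
      rows <- c(rows, list(
        tibble(stratum = s,
               metric = if (is_fall) "sensitivity" else "specificity",
               value = rate(mask, if (is_fall) "fall" else "adl")$value,
               n = sum(mask))))
    }
  }
  bind_rows(rows)
}
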