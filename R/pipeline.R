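#' Whole-pipeline configuration
#'
#' One global seed fans out deterministically to the clustering, weight
#' initialization, augmentation and data-splitting RNGs, so a full
#' training run is reproducible end to end.
#'
#' @param threshold_g Detection threshold on raw magnitude, in g.
#' @param debounce_s Trigger debounce, in seconds.
#' @param per_axis Use per-axis wavelet features (39-dim) instead of the
#'   magnitude signal (13-dim).
#' @param regpso A [regpso_config()].
#' @param fusion A [fusion_config()].
#' @param rprop An [rprop_config()] shared by both networks.
#' @param synth A [synth_config()] for simulated data.
#' @param split_ratio Training : validation ratio (4 means 4:1).
#' @param tie_rule Ensemble tie-break label.
#' @param seed Global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold_g = 1.8, debounce_s = 2.5,
                            per_axis = FALSE,
                            regpso = regpso_config(),
                            fusion = fusion_config(),
                            rprop = rprop_config(),
                            synth = synth_config(),
                            split_ratio = 4, seed = 1L) {
  stopifnot(split_ratio > 0)
  seed <- as.integer(seed)
  regpso$seed <- derive_seed(seed, 1L)
  fusion$seed <- derive_seed(seed, 2L)
  rprop$seed <- derive_seed(seed, 3L)
  synth$seed <- derive_seed(seed, 4L)
  structure(list(threshold_g = threshold_g, debounce_s = debounce_s,
                 per_axis = per_axis, regpso = regpso, fusion = fusion,
                 rprop = rprop, synth = synth, split_ratio = split_ratio,
                 tie_rule = "fall", seed = seed),
            class = "pipeline_config")
}

#' Stratified training / validation split
#'
#' Splits a labeled set by class at the given ratio (default 4:1), with
#' per-stratum sizes within one observation of the exact ratio. A class
#' with fewer than two members goes entirely to training with a warning.
#'
#' @param data Tibble with a `label` column.
#' @param ratio Training : validation ratio.
#' @param seed Integer seed for the random draw.
#' @return A list with disjoint tibbles `train` and `validation` whose
#'   union is the input.
#' @export
split_dataset <- function(data, ratio = 4, seed = 1L) {
  if (nrow(data) == 0) abort("cannot split an empty dataset")
  with_seed(seed, {
    val_idx <- integer()
    for (lab in unique(data$label)) {
      idx <- which(data$label == lab)
      if (length(idx) < 2) {
        warn(sprintf("class '%s' has fewer than 2 members; all assigned to training", lab))
        next
      }
      n_val <- floor(length(idx) / (ratio + 1))
      if (n_val > 0) val_idx <- c(val_idx, sample(idx, n_val))
    }
    list(train = data[setdiff(seq_len(nrow(data)), val_idx), , drop = FALSE],
         validation = data[sort(val_idx), , drop = FALSE])
  })
}

#' Train the full fall-detection system
#'
#' Executes the training pipeline in order: featurize the windows, build
#' the clustered-knowledge database with RegPSO, split 4:1 into training
#' and validation, train the MLP with resilient backpropagation, then
#' freeze the RBF layer on the cluster statistics and train the ARBF
#' augmentation network, and finally assemble the majority-vote ensemble.
#'
#' @param data Labeled windows (tibble with a `window` list-column, as
#'   from [gen_dataset()]) or an already-featurized tibble with `f*`
#'   columns and `label`.
#' @param config A [pipeline_config()].
#' @return A `fall_ensemble` whose `report` element logs the clustering
#'   fitness trace, validation curves, split sizes, seeds and a config
#'   echo.
#' @export
train_fall_detector <- function(data, config = pipeline_config()) {
  features <- if ("window" %in% names(data)) {
    featurize(data, per_axis = config$per_axis)
  } else data
  if (!"label" %in% names(features)) abort("training data must be labeled")
  cm <- cluster_regpso(features, config$regpso)
  parts <- split_dataset(features, ratio = config$split_ratio,
                         seed = derive_seed(config$seed, 5L))
  mlp <- train_mlp(parts$train, parts$validation, config$rprop)
  arbf_cfg <- config$rprop
  arbf_cfg$seed <- derive_seed(config$seed, 6L)
  arbf <- train_arbf(parts$train, parts$validation, cm, arbf_cfg)
  model <- fall_ensemble(mlp, arbf, cm, config$fusion,
                         tie_rule = config$tie_rule)
  model$report <- list(
    n_train = nrow(parts$train), n_validation = nrow(parts$validation),
    cluster_fitness = cm$fitness, fitness_trace = cm$trace,
    regroups = cm$regroups,
    mlp_val_curve = mlp$val_curve, arbf_val_curve = arbf$val_curve,
    seed = config$seed, config = config)
  model
}

#' Evaluate the ensemble and its members on a labeled test set
#'
#' Mirrors the three-way comparison of the single classifiers against the
#' combined one: sensitivity and specificity per stratum for ARBF alone,
#' MLP alone, and the ensemble.
#'
#' @param model A trained `fall_ensemble`.
#' @param test Labeled windows or feature tibble.
#' @param per_axis Must match the training featurization.
#' @return Tidy tibble with columns `classifier`, `stratum`, `metric`,
#'   `value`, `n`.
#' @export
evaluate_fall_detector <- function(model, test, per_axis = FALSE) {
  features <- if ("window" %in% names(test)) {
    featurize(test, per_axis = per_axis)
  } else test
  if (nrow(features) == 0) abort("empty test set")
  preds <- list(
    arbf = predict(model$arbf, features),
    mlp = predict(model$mlp, features),
    ensemble = predict(model, features)
  )
  bind_rows(lapply(names(preds), function(cls) {
    out <- evaluate_predictions(features, preds[[cls]])
    out$classifier <- cls
    out
  }))[, c("classifier", "stratum", "metric", "value", "n")]
}

#' Run streaming fall detection
#'
#' Applies the deployed pipeline to a continuous stream: trigger
#' detection, windowing, preprocessing and ensemble classification per
#' trigger. Windows that cannot be extracted (stream edge, or a gap larger
#' than one sample period) are skipped with a warning.
#'
#' @param stream Stream tibble (`time_s, ax_g, ay_g, az_g`).
#' @param model A trained `fall_ensemble`.
#' @param threshold_g,debounce_s Detection parameters.
#' @param per_axis Must match the training featurization.
#' @return Detection log: tibble with `tau`, `decision`, `votes_fall`,
#'   `votes_adl`, ordered by `tau`.
#' @export
detect_falls <- function(stream, model, threshold_g = 1.8, debounce_s = 2.5,
                         per_axis = FALSE) {
  triggers <- detect_impacts(stream, threshold_g, debounce_s)
  rows <- list()
  for (k in seq_len(nrow(triggers))) {
    tau <- triggers$tau[k]
    feat <- tryCatch({
      w <- extract_window(stream, tau)
      preprocess_window(w, per_axis = per_axis)
    }, error = function(e) {
      warn(sprintf("skipping window at tau = %.2f s: %s", tau,
                   conditionMessage(e)))
      NULL
    })
    if (is.null(feat)) next
    tally <- predict(model, matrix(feat, nrow = 1), type = "tally")
    rows <- c(rows, list(tibble(tau = tau, decision = tally$label,
                                votes_fall = tally$votes_fall,
                                votes_adl = tally$votes_adl)))
  }
  if (length(rows) == 0) {
    return(tibble(tau = numeric(), decision = character(),
                  votes_fall = integer(), votes_adl = integer()))
  }
  arrange(bind_rows(rows), .data$tau)
}

#' Score a detection log against ground-truth events
#'
#' A detection counts as a true positive when a ground-truth fall lies
#' within `tol_s` of its trigger time.
#'
#' @param log Detection log from [detect_falls()].
#' @param events Ground-truth events (`time_s`, `label`).
#' @param tol_s Matching tolerance in seconds.
#' @return Tibble with `n_events`, `n_falls`, `falls_detected`,
#'   `false_alarms`.
#' @export
score_detections <- function(log, events, tol_s = 2.5) {
  fall_times <- events$time_s[events$label == "fall"]
  detected <- vapply(fall_times, function(tt) {
    any(abs(log$tau - tt) <= tol_s & log$decision == "fall")
  }, logical(1))
  fa <- vapply(seq_len(nrow(log)), function(i) {
    log$decision[i] == "fall" && !any(abs(log$tau[i] - fall_times) <= tol_s)
  }, logical(1))
  tibble(n_events = nrow(events), n_falls = length(fall_times),
         falls_detected = sum(detected), false_alarms = sum(fa))
}

#' Serialize a trained model to a versioned text document
#'
#' The model bundle (both networks, cluster statistics, fusion
#' configuration and seeds) is written as JSON at full numeric precision,
#' so a reloaded model reproduces predictions exactly and identical
#' training runs produce byte-identical files.
#'
#' @param model A `fall_ensemble`.
#' @param path Output file path.
#' @return `read_fall_model()` returns the restored `fall_ensemble`;
#'   the writer returns `path` invisibly.
#' @export
write_fall_model <- function(model, path) {
  doc <- list(schema = "fallsense/ensemble", schema_version = 1L,
              payload = model)
  writeLines(jsonlite::serializeJSON(doc, digits = NA), path)
  invisible(path)
}

#' @rdname write_fall_model
#' @export
read_fall_model <- function(path) {
  doc <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  if (!identical(doc$schema, "fallsense/ensemble")) {
    abort("not a fallsense model file")
  }
  doc$payload
}
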