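#' Detect uncommon accelerations in a stream
#'
#' Scans a time-ordered tri-axial stream for samples whose raw magnitude
#' exceeds `threshold_g`. Each burst yields one trigger at the first
#' crossing sample; further crossings within `debounce_s` of an accepted
#' trigger are suppressed so a single impact does not spawn overlapping
#' windows.
#'
#' @param stream Tibble with columns `time_s, ax_g, ay_g, az_g`,
#'   time-ordered.
#' @param threshold_g Detection threshold on the raw magnitude, in g.
#' @param debounce_s Minimum spacing between accepted triggers, in seconds.
#' @return Tibble with one row per trigger: `tau` (s) and `peak_g`, the
#'   maximum magnitude of the contiguous super-threshold run starting at
#'   the trigger.
#' @export
detect_impacts <- function(stream, threshold_g = 1.8, debounce_s = 2.5) {
  stopifnot(threshold_g > 0, debounce_s >= 0)
  stream <- as_tibble(stream)
  if (nrow(stream) == 0) return(tibble(tau = numeric(), peak_g = numeric()))
  if (is.unsorted(stream$time_s, strictly = FALSE)) {
    abort("stream timestamps must be non-decreasing")
  }
  mag <- sqrt(stream$ax_g^2 + stream$ay_g^2 + stream$az_g^2)
  over <- which(mag > threshold_g)
  if (length(over) == 0) return(tibble(tau = numeric(), peak_g = numeric()))
  taus <- numeric()
  peaks <- numeric()
  last <- -Inf
  i <- 1
  while (i <= length(over)) {
    idx <- over[i]
    t0 <- stream$time_s[idx]
    if (t0 - last >= debounce_s || length(taus) == 0) {
      # peak over the contiguous run of super-threshold samples
      j <- idx
      while (j < nrow(stream) && mag[j + 1] > threshold_g) j <- j + 1
      taus <- c(taus, t0)
      peaks <- c(peaks, max(mag[idx:j]))
      last <- t0
    }
    i <- i + 1
  }
  tibble(tau = taus, peak_g = peaks)
}

#' Extract a 5-second window around a trigger time
#'
#' Snaps `tau` to the nearest sample and returns the 100 samples spanning
#' the half-open interval from 2.5 s before to 2.5 s after it.
#'
#' @param stream Stream tibble at the nominal sampling rate.
#' @param tau Trigger time in seconds.
#' @param sampling_hz Sampling rate (20 Hz nominal).
#' @param window_s Window length in seconds.
#' @return An acceleration window: tibble of `window_s * sampling_hz`
#'   samples with attributes `tau` and `sampling_hz`.
#' @export
extract_window <- function(stream, tau, sampling_hz = 20, window_s = 5) {
  stream <- as_tibble(stream)
  n_w <- round(window_s * sampling_hz)
  half <- n_w %/% 2
  i0 <- which.min(abs(stream$time_s - tau))
  lo <- i0 - half
  hi <- i0 + half - 1
  if (lo < 1) {
    abort(sprintf("window for tau = %g extends before the stream start (needs t = %g)",
                  tau, tau - window_s / 2))
  }
  if (hi > nrow(stream)) {
    abort(sprintf("window for tau = %g extends past the stream end (needs t = %g)",
                  tau, tau + window_s / 2))
  }
  w <- stream[lo:hi, , drop = FALSE]
  dt <- diff(w$time_s)
  if (any(abs(dt - 1 / sampling_hz) > 1e-6)) {
    abort("window samples are not uniformly spaced at the nominal rate")
  }
  attr(w, "tau") <- stream$time_s[i0]
  attr(w, "sampling_hz") <- sampling_hz
  class(w) <- c("accel_window", class(w))
  w
}

#' Normalize a window against its first sample
#'
#' Removes the gravity offset, which depends on the (arbitrary) sensor
#' orientation, by subtracting the window's first acceleration vector from
#' every sample. Idempotent.
#'
#' @param w An acceleration window.
#' @return The normalized window; its first sample is (0, 0, 0).
#' @export
normalize_window <- function(w) {
  w$ax_g <- w$ax_g - w$ax_g[1]
  w$ay_g <- w$ay_g - w$ay_g[1]
  w$az_g <- w$az_g - w$az_g[1]
  w
}

#' Magnitude signal of a window
#'
#' @param w An acceleration window (normally after [normalize_window()]).
#' @return Numeric vector of per-sample Euclidean norms, same length as the
#'   window.
#' @export
magnitude_signal <- function(w) {
  sqrt(w$ax_g^2 + w$ay_g^2 + w$az_g^2)
}

#' Haar low-pass wavelet cascade
#'
#' Applies `levels` stages of Haar low-pass filtering (coefficients
#' \eqn{1/\sqrt2, 1/\sqrt2}) followed by dyadic down-sampling, keeping only
#' the approximation path. Odd-length intermediates are zero-padded on the
#' right, so each stage maps length n to ceiling(n/2): a 100-sample signal
#' becomes 50, then 25, then 13 values.
#'
#' @param x Numeric vector, non-empty.
#' @param levels Number of cascade stages (default 3).
#' @return Numeric vector of length `ceiling^levels(length(x)/2)`.
#' @export
haar_dwt <- function(x, levels = 3) {
  if (length(x) == 0) abort("haar_dwt: empty input")
  stopifnot(levels >= 1)
  for (k in seq_len(levels)) {
    if (length(x) %% 2 == 1) x <- c(x, 0)
    even <- seq(2, length(x), by = 2)
    x <- (x[even - 1] + x[even]) / sqrt(2)
  }
  x
}

#' Reduce a raw window to its feature vector
#'
#' Composition of [normalize_window()], [magnitude_signal()] and
#' [haar_dwt()]: a 100-sample raw window becomes a 13-dimensional
#' approximation of its normalized magnitude signal. With
#' `per_axis = TRUE` the cascade is applied to each normalized axis
#' instead, giving 39 dimensions.
#'
#' @param w An acceleration window.
#' @param per_axis Process each axis separately instead of the magnitude.
#' @param levels Wavelet cascade depth.
#' @return Numeric feature vector (length 13 for a 100-sample window).
#' @export
preprocess_window <- function(w, per_axis = FALSE, levels = 3) {
  w <- normalize_window(w)
  if (per_axis) {
    c(haar_dwt(w$ax_g, levels), haar_dwt(w$ay_g, levels),
      haar_dwt(w$az_g, levels))
  } else {
    haar_dwt(magnitude_signal(w), levels)
  }
}

#' Featurize a labeled window dataset
#'
#' Maps every window of a generated (or loaded) dataset through
#' [preprocess_window()] and returns one row per window with feature
#' columns `f1..f13` alongside the labels.
#'
#' @param data Tibble with a `window` list-column and optionally `label`,
#'   `substratum`, `id` columns (as produced by [gen_dataset()]).
#' @param per_axis Passed to [preprocess_window()].
#' @return Tibble of features plus any label columns present.
#' @export
featurize <- function(data, per_axis = FALSE) {
  feats <- t(vapply(data$window, preprocess_window,
                    numeric(if (per_axis) 39 else 13), per_axis = per_axis))
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  out <- as_tibble(feats)
  for (col in c("id", "label", "substratum")) {
    if (col %in% names(data)) out[[col]] <- data[[col]]
  }
  out
}

feature_cols <- function(df) grep("^f[0-9]+$", names(df), value = TRUE)

#' Write / read labeled feature sets
#'
#' Delimited text with the feature columns and a `label` column coded
#' fall = 1, adl = 0 (plus `substratum` when present).
#'
#' @param features Feature tibble from [featurize()].
#' @param path File path.
#' @return `read_features()` returns a tibble with `label` restored to
#'   `"fall"`/`"adl"`.
#' @export
write_features <- function(features, path) {
  df <- as.data.frame(features)
  if ("label" %in% names(df)) {
    df$label <- as.integer(df$label == "fall")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- as_tibble(utils::read.csv(path, comment.char = "#"))
  if ("label" %in% names(df)) {
    df$label <- ifelse(df$label == 1, "fall", "adl")
  }
  df
}
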