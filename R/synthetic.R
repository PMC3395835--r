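#' Configuration for the synthetic accelerometer signal generator
#'
#' Bundles the parameters that control the simulated waist-worn tri-axial
#' accelerometer. The generator emulates the two signal classes the detector
#' must separate: falls, which combine a high-magnitude impact with a
#' persistent posture change (a drift between the starting and final
#' acceleration vectors), and activities of daily living (ADL), which may
#' contain impacts (sitting down, gym exercise) but no posture drift.
#'
#' @param sampling_hz Sampling rate in Hz. The pipeline assumes 20 Hz.
#' @param window_s Window length in seconds (5 s -> 100 samples at 20 Hz).
#' @param gravity_g Magnitude of the static gravity vector, in g.
#' @param impact_peak_g Length-2 range (g) for the peak magnitude of a fall
#'   impact. The lower end must exceed the detection threshold.
#' @param sit_peak_g Range (g) for the peak of a sit-down impact.
#' @param exercise_peak_g Range (g) for exercise burst peaks; above the
#'   detection threshold but below the fall range.
#' @param impact_width_s Range (s) for the half-sine impact burst width.
#' @param posture_drift_g Range (g) for the norm of the start-to-end
#'   acceleration offset of a fall.
#' @param noise_sd_g Standard deviation (g) of additive per-axis Gaussian
#'   sensor noise.
#' @param sway_amp_g Amplitude (g) of the slow sinusoidal body sway added to
#'   routine activity.
#' @param exercise_burst_rate Expected exercise bursts per second.
#' @param seed Integer seed; `NULL` uses the ambient RNG.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(sampling_hz = 20,
                         window_s = 5,
                         gravity_g = 1.0,
                         impact_peak_g = c(2.5, 5.0),
                         sit_peak_g = c(1.9, 2.5),
                         exercise_peak_g = c(1.9, 2.8),
                         impact_width_s = c(0.1, 0.3),
                         posture_drift_g = c(0.5, 1.0),
                         noise_sd_g = 0.05,
                         sway_amp_g = 0.15,
                         exercise_burst_rate = 1.0,
                         seed = NULL) {
  stopifnot(sampling_hz > 0, window_s > 0, gravity_g > 0,
            length(impact_peak_g) == 2, length(posture_drift_g) == 2,
            noise_sd_g >= 0, exercise_burst_rate > 0)
  if (min(posture_drift_g) <= 3 * noise_sd_g) {
    abort("posture_drift_g minimum must exceed 3 * noise_sd_g for falls to be well defined")
  }
  structure(
    list(sampling_hz = sampling_hz, window_s = window_s, gravity_g = gravity_g,
         impact_peak_g = impact_peak_g, sit_peak_g = sit_peak_g,
         exercise_peak_g = exercise_peak_g, impact_width_s = impact_width_s,
         posture_drift_g = posture_drift_g, noise_sd_g = noise_sd_g,
         sway_amp_g = sway_amp_g, exercise_burst_rate = exercise_burst_rate,
         seed = seed),
    class = "synth_config"
  )
}

random_unit3 <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Amplitude A such that |base + A * u| = peak (largest real root).
solve_burst_amplitude <- function(base, u, peak) {
  b <- sum(base * u)
  disc <- b^2 + peak^2 - sum(base^2)
  if (disc < 0) return(0)
  -b + sqrt(disc)
}

# Half-sine burst profile centered at t0 with total width w, evaluated at t.
burst_profile <- function(t, t0, w) {
  p <- cos(pi * (t - t0) / w)
  p[abs(t - t0) > w / 2] <- 0
  p
}

window_times <- function(cfg) {
  n <- round(cfg$window_s * cfg$sampling_hz)
  seq(-cfg$window_s / 2, by = 1 / cfg$sampling_hz, length.out = n)
}

new_accel_window <- function(t, a, tau = 0, sampling_hz = 20) {
  w <- tibble(time_s = t, ax_g = a[, 1], ay_g = a[, 2], az_g = a[, 3])
  attr(w, "tau") <- tau
  attr(w, "sampling_hz") <- sampling_hz
  class(w) <- c("accel_window", class(w))
  w
}

# Shared builder: gravity baseline + optional posture drift + impact bursts
# + noise. Burst amplitudes are solved against the noisy center sample so
# the drawn peak magnitude is met exactly by construction.
build_window <- function(cfg, bursts, drift_g = 0) {
  t <- window_times(cfg)
  n <- length(t)
  g0 <- cfg$gravity_g * random_unit3()
  base <- matrix(rep(g0, each = n), ncol = 3)
  if (drift_g > 0) {
    u_drift <- random_unit3()
    s <- 1 / (1 + exp(-(t - 0.25) / 0.06))
    base <- base + outer(s, drift_g * u_drift)
  }
  noise <- matrix(rnorm(3 * n, sd = cfg$noise_sd_g), ncol = 3)
  a <- base + noise
  for (b in bursts) {
    i0 <- which.min(abs(t - b$t0))
    u <- random_unit3()
    amp <- solve_burst_amplitude(a[i0, ], u, b$peak)
    prof <- burst_profile(t, t[i0], b$width)
    a <- a + outer(prof * amp, u)
  }
  new_accel_window(t, a, tau = 0, sampling_hz = cfg$sampling_hz)
}

#' Generate a single synthetic fall window
#'
#' A fall window carries a central impact spike with peak magnitude drawn
#' from `cfg$impact_peak_g` and a logistic post-impact orientation change so
#' the mean acceleration of the final second differs from that of the first
#' second by a drift drawn from `cfg$posture_drift_g`.
#'
#' @param cfg A [synth_config()].
#' @param seed Optional integer seed.
#' @return A one-row tibble with columns `label`, `substratum` and a
#'   list-column `window` holding the 100-sample acceleration window.
#' @export
gen_fall_window <- function(cfg = synth_config(), seed = NULL) {
  with_seed(seed, {
    peak <- runif(1, cfg$impact_peak_g[1], cfg$impact_peak_g[2])
    width <- runif(1, cfg$impact_width_s[1], cfg$impact_width_s[2])
    drift <- runif(1, cfg$posture_drift_g[1], cfg$posture_drift_g[2])
    w <- build_window(cfg, list(list(t0 = 0, peak = peak, width = width)),
                      drift_g = drift)
    tibble(label = "fall", substratum = "fall", window = list(w))
  })
}

#' Generate a single synthetic ADL window
#'
#' Three sub-strata are supported: `sit_down` (an impact with no posture
#' change), `routine` (quiet activity whose magnitude never reaches the
#' detection threshold), and `exercise` (repeated impact bursts, again with
#' no posture change).
#'
#' @param cfg A [synth_config()].
#' @param substratum One of `"sit_down"`, `"routine"`, `"exercise"`.
#' @param seed Optional integer seed.
#' @return A one-row tibble as in [gen_fall_window()], with `label = "adl"`.
#' @export
gen_adl_window <- function(cfg = synth_config(),
                           substratum = c("sit_down", "routine", "exercise"),
                           seed = NULL) {
  substratum <- match.arg(substratum)
  with_seed(seed, {
    w <- switch(
      substratum,
      sit_down = {
        peak <- runif(1, cfg$sit_peak_g[1], cfg$sit_peak_g[2])
        width <- runif(1, cfg$impact_width_s[1], cfg$impact_width_s[2])
        build_window(cfg, list(list(t0 = 0, peak = peak, width = width)))
      },
      routine = {
        t <- window_times(cfg)
        g0 <- cfg$gravity_g * random_unit3()
        freq <- runif(1, 0.3, 1)
        sway <- cfg$sway_amp_g * sin(2 * pi * freq * t + runif(1, 0, 2 * pi))
        a <- matrix(rep(g0, each = length(t)), ncol = 3) +
          outer(sway, random_unit3()) +
          matrix(rnorm(3 * length(t), sd = cfg$noise_sd_g), ncol = 3)
        new_accel_window(t, a, tau = 0, sampling_hz = cfg$sampling_hz)
      },
      exercise = {
        n_burst <- max(1L, stats::rpois(1, cfg$exercise_burst_rate * cfg$window_s))
        # keep bursts out of the first/last second so the start-vs-end
        # mean stays drift-free by construction
        half <- cfg$window_s / 2 - 1.1
        t0 <- sort(runif(n_burst, -half, half))
        bursts <- lapply(t0, function(tc) {
          list(t0 = tc,
               peak = runif(1, cfg$exercise_peak_g[1], cfg$exercise_peak_g[2]),
               width = runif(1, cfg$impact_width_s[1], cfg$impact_width_s[2]))
        })
        build_window(cfg, bursts)
      }
    )
    tibble(label = "adl", substratum = substratum, window = list(w))
  })
}

#' Generate a labeled dataset of synthetic windows
#'
#' @param n_fall,n_adl Window counts per class.
#' @param mix Named numeric vector of ADL substratum proportions, allocated
#'   by largest-remainder rounding. Default 3:1 routine to exercise with no
#'   explicit sit-down stratum; include `sit_down` to add it.
#' @param cfg A [synth_config()].
#' @param seed Integer seed; the default uses `cfg$seed`.
#' @return A tibble with columns `id`, `label`, `substratum`, `window`
#'   (list-column of windows), shuffled.
#' @export
gen_dataset <- function(n_fall, n_adl,
                        mix = c(routine = 3, exercise = 1),
                        cfg = synth_config(), seed = cfg$seed) {
  stopifnot(n_fall >= 0, n_adl >= 0, all(mix >= 0), sum(mix) > 0)
  with_seed(seed, {
    counts <- largest_remainder(n_adl, mix / sum(mix))
    rows <- list()
    if (n_fall > 0) {
      rows <- c(rows, lapply(seq_len(n_fall), function(i) gen_fall_window(cfg)))
    }
    for (s in names(counts)) {
      if (counts[[s]] > 0) {
        rows <- c(rows, lapply(seq_len(counts[[s]]),
                               function(i) gen_adl_window(cfg, s)))
      }
    }
    if (length(rows) == 0) {
      return(tibble(id = integer(), label = character(),
                    substratum = character(), window = list()))
    }
    out <- bind_rows(rows)
    out <- out[sample.int(nrow(out)), ]
    out$id <- seq_len(nrow(out))
    out[, c("id", "label", "substratum", "window")]
  })
}

largest_remainder <- function(total, p) {
  raw <- total * p
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

#' Generate a continuous accelerometer stream with scheduled events
#'
#' Splices fall / sit-down / exercise events onto a quiet routine baseline,
#' for end-to-end testing of detection, windowing and classification. A
#' fall's posture drift turns on after the impact and relaxes back about 4
#' seconds later, so consecutive events do not interact.
#'
#' @param duration_s Stream length in seconds.
#' @param events A data frame with columns `time_s` and
#'   `type` (`"fall"`, `"sit_down"` or `"exercise"`); may be empty.
#' @param cfg A [synth_config()].
#' @param seed Optional integer seed.
#' @return A list with `stream` (tibble `time_s, ax_g, ay_g, az_g`) and
#'   `events` (ground truth with `time_s`, `type`, `label`).
#' @export
gen_stream <- function(duration_s, events = NULL, cfg = synth_config(),
                       seed = cfg$seed) {
  if (is.null(events)) {
    events <- tibble(time_s = numeric(), type = character())
  }
  events <- as_tibble(events)
  if (nrow(events) > 0) {
    events <- arrange(events, .data$time_s)
    margin <- cfg$window_s / 2 + 2.5
    if (any(events$time_s < margin) ||
        any(events$time_s > duration_s - margin)) {
      abort("events must lie at least 5 s from the stream edges")
    }
    if (any(diff(events$time_s) < 5)) {
      abort("overlapping events: schedule them at least 5 s apart")
    }
  }
  with_seed(seed, {
    n <- round(duration_s * cfg$sampling_hz)
    t <- seq(0, by = 1 / cfg$sampling_hz, length.out = n)
    g0 <- cfg$gravity_g * random_unit3()
    a <- matrix(rep(g0, each = n), ncol = 3) +
      matrix(rnorm(3 * n, sd = cfg$noise_sd_g), ncol = 3)
    for (k in seq_len(nrow(events))) {
      tau <- events$time_s[k]
      type <- events$type[k]
      if (!type %in% c("fall", "sit_down", "exercise")) {
        abort(paste0("unknown event type: ", type))
      }
      add_event <- function(peak, width, t0) {
        i0 <- which.min(abs(t - t0))
        u <- random_unit3()
        amp <- solve_burst_amplitude(a[i0, ], u, peak)
        prof <- burst_profile(t, t[i0], width)
        a <<- a + outer(prof * amp, u)
      }
      if (type == "fall") {
        peak <- runif(1, cfg$impact_peak_g[1], cfg$impact_peak_g[2])
        width <- runif(1, cfg$impact_width_s[1], cfg$impact_width_s[2])
        drift <- runif(1, cfg$posture_drift_g[1], cfg$posture_drift_g[2])
        add_event(peak, width, tau)
        s_on <- 1 / (1 + exp(-(t - (tau + 0.25)) / 0.06))
        s_off <- 1 / (1 + exp(-(t - (tau + 4)) / 0.06))
        a <- a + outer(s_on - s_off, drift * random_unit3())
      } else if (type == "sit_down") {
        add_event(runif(1, cfg$sit_peak_g[1], cfg$sit_peak_g[2]),
                  runif(1, cfg$impact_width_s[1], cfg$impact_width_s[2]), tau)
      } else {
        for (dt in c(-0.6, 0, 0.6)) {
          add_event(runif(1, cfg$exercise_peak_g[1], cfg$exercise_peak_g[2]),
                    runif(1, cfg$impact_width_s[1], cfg$impact_width_s[2]),
                    tau + dt)
        }
      }
    }
    stream <- tibble(time_s = t, ax_g = a[, 1], ay_g = a[, 2], az_g = a[, 3])
    truth <- mutate(events,
                    label = ifelse(.data$type == "fall", "fall", "adl"))
    list(stream = stream, events = truth)
  })
}

#' Write / read the delimited stream and labeled-window formats
#'
#' Streams are comma-delimited text with header `time_s,ax_g,ay_g,az_g`;
#' lines starting with `#` are comments. Labeled feature sets carry the 13
#' feature columns plus `label` (fall = 1, adl = 0).
#'
#' @param stream A stream tibble.
#' @param path File path.
#' @return `read_stream()` returns a tibble; writers return `path`
#'   invisibly.
#' @export
write_stream <- function(stream, path) {
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time_s", "ax_g", "ay_g", "az_g")
  if (!all(need %in% names(df))) {
    abort("stream file must have columns time_s, ax_g, ay_g, az_g")
  }
  as_tibble(df[, need])
}
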