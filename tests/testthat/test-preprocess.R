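test_that("impact detection finds threshold crossings and debounces them", {
  hz <- 20
  t <- seq(0, 20 - 1 / hz, by = 1 / hz)
  quiet <- tibble::tibble(time_s = t, ax_g = 0, ay_g = 0, az_g = 1)

  expect_equal(nrow(detect_impacts(quiet, threshold_g = 1.8)), 0)
  expect_equal(nrow(detect_impacts(quiet[0, ], threshold_g = 1.8)), 0)

  spike <- quiet
  spike$az_g[t == 10] <- 3
  hit <- detect_impacts(spike, threshold_g = 1.8)
  expect_equal(hit$tau, 10.0)
  expect_equal(hit$peak_g, 3)

  # crossings at 10.00 and 10.05 with a 2.5 s debounce collapse to one event
  two <- quiet
  two$az_g[t %in% c(10.00, 10.05)] <- c(3, 2.5)
  got <- detect_impacts(two, threshold_g = 1.8, debounce_s = 2.5)
  expect_equal(got$tau, 10.00)

  bad <- quiet[c(2, 1, 3), ]
  expect_error(detect_impacts(bad), "non-decreasing")
})

test_that("detection equals a brute-force threshold scan thinned by debounce", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 400
    t <- seq(0, by = 0.05, length.out = n)
    az <- 1 + (runif(n) < 0.05) * runif(n, 1, 3)
    stream <- tibble::tibble(time_s = t, ax_g = 0, ay_g = 0, az_g = az)
    thr <- 1.8
    deb <- 1.0
    # oracle: scan crossings in order, greedily accept spaced >= debounce
    crossings <- t[abs(az) > thr]
    keep <- numeric()
    for (tt in crossings) {
      if (length(keep) == 0 || tt - keep[length(keep)] >= deb) keep <- c(keep, tt)
    }
    got <- detect_impacts(stream, threshold_g = thr, debounce_s = deb)
    expect_equal(got$tau, keep)
    expect_true(all(sqrt(stream$az_g[stream$time_s %in% got$tau]^2) > thr))
  }
})

test_that("window extraction returns exactly 100 samples around tau", {
  hz <- 20
  t <- seq(0, 20 - 1 / hz, by = 1 / hz)
  stream <- tibble::tibble(time_s = t, ax_g = 0, ay_g = 0, az_g = 1)

  w <- extract_window(stream, tau = 10)
  expect_equal(nrow(w), 100)
  expect_equal(w$time_s[1], 7.50)
  expect_equal(w$time_s[100], 12.45)
  expect_equal(attr(w, "tau"), 10)

  expect_error(extract_window(stream, tau = 1.0), "before the stream start")
  expect_error(extract_window(stream, tau = 19.5), "past the stream end")

  # a 100-sample stream with tau at its exact center is returned whole
  short <- stream[1:100, ]
  w2 <- extract_window(short, tau = short$time_s[51])
  expect_equal(w2$time_s, short$time_s)

  # off-grid tau snaps to the nearest sample
  w3 <- extract_window(stream, tau = 10.01)
  expect_equal(attr(w3, "tau"), 10)

  gappy <- stream[-150, ]
  expect_error(extract_window(gappy, tau = 7.5), "uniformly spaced")
})

test_that("normalization subtracts the first sample and is idempotent", {
  w <- make_quiet_window()
  n1 <- normalize_window(w)
  expect_true(all(n1$ax_g == 0) && all(n1$ay_g == 0) && all(n1$az_g == 0))

  w$ax_g[10] <- 0.1
  w$az_g[10] <- 1.2
  n2 <- normalize_window(w)
  expect_equal(c(n2$ax_g[1], n2$ay_g[1], n2$az_g[1]), c(0, 0, 0))
  expect_equal(c(n2$ax_g[10], n2$ay_g[10], n2$az_g[10]), c(0.1, 0, 0.2))
  expect_identical(normalize_window(n2), n2)
})

test_that("magnitude signal is the per-sample Euclidean norm", {
  w <- make_quiet_window()
  w$ax_g[5] <- 3; w$ay_g[5] <- 4; w$az_g[5] <- 0
  m <- magnitude_signal(w)
  expect_length(m, 100)
  expect_equal(m[5], 5)
  w0 <- normalize_window(make_quiet_window())
  expect_equal(magnitude_signal(w0), rep(0, 100))
})

test_that("Haar cascade obeys the ceil(n/2) length law and scaling identities", {
  expect_length(haar_dwt(rnorm(100), 3), 13)    # 100 -> 50 -> 25 -> 13
  expect_length(haar_dwt(rnorm(100), 1), 50)
  expect_length(haar_dwt(rnorm(100), 2), 25)
  expect_equal(haar_dwt(rep(0, 100)), rep(0, 13))
  # constant length-8 input: each low-pass stage scales a constant by sqrt(2)
  expect_equal(haar_dwt(rep(3, 8), 3), 2 * sqrt(2) * 3)
  expect_error(haar_dwt(numeric(0)), "empty")

  set.seed(7)
  for (n in c(1, 5, 13, 64, 100, 101)) {
    s <- rnorm(n)
    len <- n
    for (k in 1:3) len <- ceiling(len / 2)
    out <- haar_dwt(s, 3)
    expect_length(out, len)
    # linearity and per-stage max-amplitude growth bound
    expect_equal(haar_dwt(2.5 * s, 3), 2.5 * out, tolerance = 1e-9)
    expect_lte(max(abs(haar_dwt(s, 1))), sqrt(2) * max(abs(s)) + 1e-12)
  }
})

test_that("preprocessing composes to a 13-dim feature and kills constant windows", {
  expect_equal(preprocess_window(make_quiet_window()), rep(0, 13))

  sim <- gen_fall_window(synth_config(), seed = 3)
  w <- sim$window[[1]]
  f1 <- preprocess_window(w)
  expect_length(f1, 13)
  expect_identical(preprocess_window(w), f1)
  expect_equal(f1, haar_dwt(magnitude_signal(normalize_window(w)), 3))
  expect_length(preprocess_window(w, per_axis = TRUE), 39)
})

test_that("feature files round-trip with integer-coded labels", {
  ds <- gen_dataset(4, 4, cfg = synth_config(), seed = 5)
  ft <- featurize(ds)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(ft, path)
  line1 <- readLines(path, n = 2)[2]
  expect_false(grepl("fall|adl", line1))
  back <- read_features(path)
  expect_equal(back$label, ft$label)
  expect_equal(as.matrix(back[, paste0("f", 1:13)]),
               as.matrix(ft[, paste0("f", 1:13)]), tolerance = 1e-6)
})
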