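make_stream <- function(channels, cfg = quick_config()) {
  signal_stream(channels, cfg$sample_rate, cfg$frequencies)
}

noise_channels <- function(n, amp_sd = 0.005, ph_sd = 0.02) {
  cbind(matrix(rnorm(n * 3, sd = amp_sd), n, 3),
        matrix(rnorm(n * 3, sd = ph_sd), n, 3))
}

test_that("detrending removes slow baselines without touching event peaks", {
  cfg <- quick_config()
  # pure linear drift, no events
  n <- 8000
  drift <- seq(0, 1, length.out = n)
  st <- make_stream(cbind(drift, drift, drift, 0 * drift, 0 * drift, 0 * drift))
  out <- detrend_and_filter(st)
  expect_lt(max(abs(out$channels[, 1:3])), 0.01)
  # all-zero input stays zero
  z <- detrend_and_filter(make_stream(matrix(0, 4000, 6)))
  expect_equal(max(abs(z$channels)), 0)
  # clean event + drift: second-peak amplitude preserved within 2%
  ev <- signal_channels(clean_event(bead_particle(10), "T1", cfg))
  pad <- matrix(0, 3000, 6)
  ch <- rbind(pad, ev, pad)
  ref <- detrend_and_filter(make_stream(ch))
  p_ref <- max(abs(ref$channels[, 1]))
  ch_drift <- ch
  # drift comparable in size to the signal peak over the whole record
  ch_drift[, 1] <- ch_drift[, 1] + seq(0, 0.5, length.out = nrow(ch))
  out <- detrend_and_filter(make_stream(ch_drift))
  expect_lt(abs(max(abs(out$channels[, 1])) - p_ref) / p_ref, 0.02)
})

test_that("detector has no false positives on pure noise at k = 5", {
  set.seed(11)
  st <- make_stream(noise_channels(1e6))
  expect_length(detect_events(st, k = 5), 0)
  expect_error(detect_events(make_stream(matrix(numeric(0), 0, 6))), "empty")
})

test_that("detector finds exactly the injected events", {
  cfg <- quick_config()
  set.seed(12)
  ev <- signal_channels(simulate_event(
    transit_event(bead_particle(8), "T1"), cfg,
    noise = noise_model(0.005, 0.02, seed = 1)))  # ~20x noise sd at peak
  parts <- list(noise_channels(500))
  for (i in 1:50) {
    parts[[2 * i]] <- ev
    parts[[2 * i + 1]] <- noise_channels(500)
  }
  st <- make_stream(do.call(rbind, parts))
  frags <- detect_events(detrend_and_filter(st), k = 5)
  expect_length(frags, 50)
})

test_that("peak extraction canonicalizes the two trajectories", {
  cfg <- quick_config()
  s1 <- clean_event(bead_particle(10), "T1", cfg)
  p1 <- extract_peaks(as_stream(s1))
  expect_true(p1$ok)
  expect_equal(p1$trajectory, "T1")
  expect_equal(dim(p1$amplitude), c(4, 3))
  for (j in 1:3) expect_equal(sign(p1$amplitude[, j]), c(1, -1, 1, -1))
  # a T2 event (time-reversed, sign-flipped) gives the identical canonical
  # second peak
  p2 <- extract_peaks(as_stream(clean_event(bead_particle(10), "T2", cfg)))
  expect_equal(p2$trajectory, "T2")
  expect_equal(p2$amplitude[2, ], p1$amplitude[2, ], tolerance = 1e-12)
  # pure noise is rejected, not dropped silently
  set.seed(13)
  bad <- extract_peaks(make_stream(noise_channels(300)))
  expect_false(bad$ok)
  expect_type(bad$reason, "character")
})

test_that("size calibration is the exact cube-root law on noiseless beads", {
  cfg <- quick_config()
  sizes <- c(7, 10, 15, 20)
  ps <- lapply(sizes, function(d)
    extract_peaks(as_stream(clean_event(bead_particle(d), "T1", cfg))))
  cal <- fit_size_calibration(ps, sizes)
  expect_true(all(cal$r_squared > 0.9999))
  expect_lt(abs(cal$intercept[2, 1]), 0.01 * max(sizes))
  expect_true(all(cal$slope > 0))
  # too few sizes
  expect_error(fit_size_calibration(ps[1:2], sizes[1:2]), "3 distinct")
})

test_that("feature arithmetic follows the definitions", {
  # equal amplitudes at all frequencies -> all opacities 1
  amp <- matrix(rep(c(2, -2, 2, -2), 3), 4, 3)
  ft <- compute_features(fake_peak_set(amp), fake_calibration())
  expect_equal(ft$opacity_1_05, 1)
  expect_equal(ft$opacity_2_05, 1)
  expect_equal(ft$opacity_2_1, 1)
  expect_equal(ft$op_theta_2_05, 1)
  # cube-root identity: amplitudes {1, 8, 27} with a = 1, b = 0
  amp2 <- rbind(0, c(1, 8, 27), 0, 0)
  fts <- lapply(1:3, function(j) {
    a <- amp2; a[2, 1] <- amp2[2, j]
    compute_features(fake_peak_set(a), fake_calibration(1, 0))
  })
  expect_equal(vapply(fts, `[[`, numeric(1), "estimated_diameter"), 1:3)
  # zero low-frequency amplitude is an error
  expect_error(compute_features(fake_peak_set(matrix(0, 4, 3)),
                                fake_calibration()), "zero")
})

test_that("bead opacity is stable across sizes and cell orderings hold", {
  cfg <- quick_config()
  sizes <- c(7, 10, 15, 20)
  ps <- lapply(sizes, function(d)
    extract_peaks(as_stream(clean_event(bead_particle(d), "T1", cfg))))
  cal <- fit_size_calibration(ps, sizes)
  ops <- vapply(ps, function(p) compute_features(p, cal)$opacity_2_05,
                numeric(1))
  expect_lt(sd(ops) / mean(ops), 0.02)
  # WBC vs MCF-7 with noise: diameter and opacity orderings
  feats <- function(preset, seed0) {
    cells <- generate_population(population_spec(preset, n = 30), seed = seed0)
    out <- lapply(seq_len(30), function(i) {
      s <- simulate_event(transit_event(cells$particles[[i]],
                                        cells$trajectories[i]), cfg,
                          noise = noise_model(seed = seed0 + i))
      pk <- extract_peaks(as_stream(s))
      if (isTRUE(pk$ok)) as.data.frame(compute_features(pk, cal))
    })
    do.call(rbind, out)
  }
  fw <- feats("WBC", 100); fm <- feats("MCF-7", 900)
  expect_gt(mean(fm$estimated_diameter), mean(fw$estimated_diameter))
  expect_lt(mean(fm$opacity_2_05), mean(fw$opacity_2_05))
})

test_that("minimum detectable size behaves like the inverted calibration", {
  cal0 <- fake_calibration(2, 0)
  # cube-root scaling when the intercept is zero
  m1 <- minimum_detectable_size(0.01, cal0)
  m2 <- minimum_detectable_size(0.02, cal0)
  expect_equal(m2 / m1, matrix(2^(1/3), 4, 3), tolerance = 1e-12)
  # noise -> 0 limit tends to max(intercept, 0)
  calb <- fake_calibration(2, 1.5)
  expect_equal(minimum_detectable_size(1e-12, calb)[1, 1], 1.5,
               tolerance = 1e-3)
  calneg <- fake_calibration(2, -1)
  expect_equal(minimum_detectable_size(1e-12, calneg)[1, 1], 0,
               tolerance = 1e-3)
  expect_error(minimum_detectable_size(0, cal0), "noise_sd")
  # on the simulator's own per-peak calibration, the second peak (strongest
  # coupling) has the smallest minimum detectable size
  cfg <- quick_config()
  sizes <- c(7, 10, 15, 20)
  ps <- lapply(sizes, function(d)
    extract_peaks(as_stream(clean_event(bead_particle(d), "T1", cfg))))
  cal <- fit_size_calibration(ps, sizes)
  mds <- minimum_detectable_size(0.005, cal, snr_threshold = 3)
  expect_true(all(mds[2, ] <= apply(mds, 2, min) + 1e-9))
})

test_that("fragments resample to the fixed 100 x 6 tensor", {
  cfg <- quick_config()
  s <- simulate_event(transit_event(bead_particle(10), "T1",
                                    speed = 0.15 * 291 / 400), cfg,
                      noise = noise_model(0, 0))
  expect_gte(nrow(s$amplitude), 395)  # ~400-sample fragment
  tens <- resample_fragment(as_stream(s))
  expect_equal(dim(tens$data), c(100, 6))
  expect_true(all(is.finite(tens$data)))
  expect_true(all(abs(tens$data) <= 1 + 1e-12))
  # 100-sample fragment: identity resampling up to the stored scales
  ch <- matrix(rnorm(600), 100, 6)
  st <- make_stream(ch)
  t2 <- resample_fragment(st)
  expect_equal(sweep(t2$data, 2, t2$scales, "*"), ch, tolerance = 1e-12)
  # constant and all-zero channels survive
  ch0 <- ch; ch0[, 2] <- 0; ch0[, 5] <- 3
  t3 <- resample_fragment(make_stream(ch0))
  expect_true(all(is.finite(t3$data)))
  expect_equal(unique(t3$data[, 2]), 0)
  expect_error(resample_fragment(make_stream(ch[1:10, ])), "short")
})

test_that("feature correlation matrix is a correlation matrix", {
  set.seed(21)
  f <- data.frame(estimated_diameter = rnorm(1e4),
                  opacity_1_05 = rnorm(1e4), opacity_2_05 = rnorm(1e4),
                  opacity_2_1 = rnorm(1e4), op_theta_2_05 = rnorm(1e4))
  cm <- feature_correlation_matrix(f)
  expect_equal(diag(cm), rep(1, 5), ignore_attr = TRUE)
  expect_lt(max(abs(cm - t(cm))), 1e-12)
  # independent columns at n = 1e4: off-diagonals within +/- 0.05
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)
  # duplicated feature -> off-diagonal 1
  f2 <- f; f2$opacity_1_05 <- f2$estimated_diameter
  expect_equal(feature_correlation_matrix(f2)["estimated_diameter",
                                              "opacity_1_05"], 1)
  # constant column flagged
  f3 <- f; f3$opacity_2_1 <- 1
  cm3 <- feature_correlation_matrix(f3)
  expect_true(any(attr(cm3, "flagged")))
  expect_error(feature_correlation_matrix(f[1:2, ]), "3")
})

test_that("diameters are recovered end to end and are trajectory-invariant", {
  cfg <- quick_config()
  sizes <- c(7, 10, 15, 20)
  ps <- lapply(sizes, function(d)
    extract_peaks(as_stream(clean_event(bead_particle(d), "T1", cfg))))
  cal <- fit_size_calibration(ps, sizes)
  for (d in c(8.5, 12, 18)) {
    for (tr in c("T1", "T2")) {
      pk <- extract_peaks(as_stream(clean_event(bead_particle(d), tr, cfg)))
      est <- compute_features(pk, cal)$estimated_diameter
      expect_lt(abs(est - d) / d, 0.005)
    }
    # exact T1/T2 equality at zero noise
    e1 <- compute_features(extract_peaks(as_stream(
      clean_event(bead_particle(d), "T1", cfg))), cal)
    e2 <- compute_features(extract_peaks(as_stream(
      clean_event(bead_particle(d), "T2", cfg))), cal)
    expect_equal(e1$estimated_diameter, e2$estimated_diameter,
                 tolerance = 1e-12)
    expect_equal(e1$opacity_2_05, e2$opacity_2_05, tolerance = 1e-12)
  }
})
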