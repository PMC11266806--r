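test_that("differential kernel has 4 sign-alternating lobes and zero integral", {
  cfg <- quick_config()
  k1 <- differential_kernel(cfg, "T1")
  x <- seq(k1$support[1], k1$support[2], length.out = 20001)
  v <- k1$fn(x)
  # local extrema above 10% of peak
  d <- sign(diff(v)); d[d == 0] <- 1
  ext <- which(diff(d) != 0) + 1
  ext <- ext[abs(v[ext]) > 0.1]
  expect_length(ext, 4)
  expect_equal(sign(v[ext]), c(1, -1, 1, -1))
  # unit peak normalization: a discrete grid can only undershoot the peak
  expect_lte(max(abs(v)), 1 + 1e-12)
  expect_gt(max(abs(v)), 1 - 1e-6)
  # numeric quadrature: differential kernel integrates to ~0
  expect_lt(abs(sum(v) * (x[2] - x[1])) / diff(k1$support), 1e-6)
})

test_that("T2 kernel is the point reflection of T1", {
  cfg <- quick_config()
  k1 <- differential_kernel(cfg, "T1")
  k2 <- differential_kernel(cfg, "T2")
  x <- seq(k1$support[1], k1$support[2], length.out = 4001)
  expect_lt(max(abs(k2$fn(x) + k1$fn(-x))), 1e-12)
})

test_that("amplitude follows the d^3 law exactly in the noiseless model", {
  cfg <- quick_config()
  a <- vapply(c(5, 10), function(d)
    max(abs(clean_event(bead_particle(d))$amplitude[, 1])), numeric(1))
  expect_equal(a[2] / a[1], 8, tolerance = 1e-6)
  # index-matched particle leaves no trace
  matched <- shelled_cell(10, membrane_thickness = 5,
                          membrane_conductivity = 1.6,
                          membrane_relative_permittivity = 78,
                          cytoplasm_conductivity = 1.6,
                          cytoplasm_relative_permittivity = 78)
  expect_lt(max(abs(clean_event(matched)$amplitude)), 1e-12)
})

test_that("T2 trace is the time-reversed, sign-flipped T1 trace", {
  cfg <- quick_config()
  for (p in list(bead_particle(10), cell_preset("MCF-7"))) {
    s1 <- clean_event(p, "T1", cfg)$amplitude
    s2 <- clean_event(p, "T2", cfg)$amplitude
    expect_lt(max(abs(s2 - (-s1[nrow(s1):1, ]))), 1e-12)
  }
})

test_that("every clean event has exactly 4 alternating peaks in every channel", {
  cfg <- quick_config()
  set.seed(7)
  for (i in 1:8) {
    p <- if (i %% 2) bead_particle(runif(1, 6, 20))
         else cell_preset(sample(c("WBC", "MCF-7", "A549", "SW480"), 1),
                          diameter = runif(1, 8, 20))
    s <- clean_event(p, sample(c("T1", "T2"), 1), cfg)
    for (j in 1:3) {
      v <- s$amplitude[, j]
      d <- sign(diff(v)); d[d == 0] <- 1
      ext <- which(diff(d) != 0) + 1
      ext <- ext[abs(v[ext]) > 0.1 * max(abs(v))]
      expect_length(ext, 4)
      expect_true(all(sign(v[ext])[-1] * sign(v[ext])[-4] == -1))
    }
  }
})

test_that("simulation is deterministic under a fixed seed", {
  ev <- transit_event(cell_preset("WBC"), "T1")
  n <- noise_model(0.01, 0.05, baseline_drift = 0.1, seed = 99)
  a <- simulate_event(ev, noise = n)
  b <- simulate_event(ev, noise = n)
  expect_identical(a$amplitude, b$amplitude)
  expect_identical(a$phase, b$phase)
  # and different seeds differ
  n2 <- n; n2$seed <- 100
  expect_false(identical(simulate_event(ev, noise = n2)$amplitude,
                         a$amplitude))
})

test_that("events too fast to resolve are rejected", {
  expect_error(simulate_event(transit_event(bead_particle(10), speed = 50)),
               "too fast")
})

test_that("lock-in recovers amplitude and phase of a constant tone", {
  fs <- 2e5
  t <- (0:19999) / fs
  z <- lockin_demodulate(1.7 * cos(2 * pi * 8000 * t + 0.8), fs, 8000, 400)
  mid <- 5000:15000
  expect_lt(max(abs(Mod(z[mid]) - 1.7)), 1e-3 * 1.7)
  expect_lt(max(abs(Arg(z[mid]) - 0.8)), 1e-3)
})

test_that("two tones demodulate to their own envelopes with <1% cross-talk", {
  fs <- 4e5
  t <- (0:39999) / fs
  e1 <- 1 + 0.5 * sin(2 * pi * 20 * t)     # slow envelopes
  e2 <- 2 + 0.3 * cos(2 * pi * 35 * t)
  s <- e1 * cos(2 * pi * 10000 * t) + e2 * cos(2 * pi * 40000 * t + 1)
  z1 <- lockin_demodulate(s, fs, 10000, 300)
  z2 <- lockin_demodulate(s, fs, 40000, 300)
  mid <- 10000:30000
  expect_lt(max(abs(Mod(z1[mid]) - e1[mid])) / max(e1), 0.01)
  expect_lt(max(abs(Mod(z2[mid]) - e2[mid])) / max(e2), 0.01)
})

test_that("carrier-level demodulation path agrees with the baseband model", {
  cfg <- quick_config()
  ev <- transit_event(cell_preset("MCF-7"), "T2")
  base <- simulate_event(ev, cfg, noise = noise_model(0, 0))
  car <- simulate_carrier_and_demodulate(ev, cfg, noise = noise_model(0, 0))
  for (j in 1:3) {
    pb <- max(abs(base$amplitude[, j]))
    pc <- max(abs(car$amplitude[, j]))
    expect_lt(abs(pc - pb) / pb, 0.02)
    expect_lt(abs(car$phase[1, j] - base$phase[1, j]), 0.02)
  }
  # aliasing / bandwidth guards
  expect_error(simulate_carrier_and_demodulate(ev, cfg, carrier_scale = 1e-3),
               "carrier")
})
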