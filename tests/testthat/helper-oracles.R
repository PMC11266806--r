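# Shared fixtures and independent oracles.

# Independent literal transcription of the shelled-sphere mixture formula and
# the dipole factor, kept deliberately separate from the package
# implementation: everything here works on raw numbers in SI units with no
# package types.
oracle_eps <- function(er, sig, f) {
  8.8541878128e-12 * er - (0+1i) * sig / (2 * pi * f)
}

oracle_shell_eps <- function(R_outer, thickness, mem_er, mem_sig,
                             cyt_er, cyt_sig, f) {
  e1 <- oracle_eps(mem_er, mem_sig, f)   # shell
  e2 <- oracle_eps(cyt_er, cyt_sig, f)   # core
  v <- ((R_outer - thickness) / R_outer)^3  # core volume fraction
  e1 * (((e2 + 2 * e1) + 2 * v * (e2 - e1)) /
          ((e2 + 2 * e1) - v * (e2 - e1)))
}

oracle_cm <- function(ep, em) (ep - em) / (ep + 2 * em)

oracle_cell_cm <- function(cell, med, f) {
  ep <- oracle_shell_eps(cell$diameter * 1e-6 / 2,
                         cell$membrane_thickness * 1e-9,
                         cell$membrane_relative_permittivity,
                         cell$membrane_conductivity,
                         cell$cytoplasm_relative_permittivity,
                         cell$cytoplasm_conductivity, f)
  oracle_cm(ep, oracle_eps(med$relative_permittivity, med$conductivity, f))
}

# small helpers used across test files
quick_config <- function(...) electrode_config(...)

clean_event <- function(particle, trajectory = "T1", config = quick_config()) {
  simulate_event(transit_event(particle, trajectory), config,
                 noise = noise_model(0, 0))
}

# hand-built peak_set for unit tests of the feature arithmetic
fake_peak_set <- function(amp, phase = matrix(1, 4, 3)) {
  structure(list(ok = TRUE, reason = NULL, amplitude = amp, phase = phase,
                 index = matrix(seq_len(4), 4, 3), trajectory = "T1",
                 frequencies = c(0.5e6, 1e6, 2e6)),
            class = "peak_set")
}

fake_calibration <- function(slope = 1, intercept = 0) {
  structure(list(slope = matrix(slope, 4, 3),
                 intercept = matrix(intercept, 4, 3),
                 r_squared = matrix(1, 4, 3),
                 frequencies = c(0.5e6, 1e6, 2e6)),
            class = "size_calibration")
}

# strongly separable synthetic fragments (not from the simulator): class 0
# carries a positive bump in channel 1, class 1 in channel 2
separable_fragments <- function(n_per_class, seed = 1, noise_sd = 0.05,
                                gap = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- array(rnorm(n * 100 * 6, sd = noise_sd), c(n, 100, 6))
  bump <- sin(seq(0, pi, length.out = 100))
  y <- rep(c("WBC", "TUMOR"), each = n_per_class)
  for (i in seq_len(n)) {
    ch <- if (y[i] == "WBC") 1 else 2
    x[i, , ch] <- x[i, , ch] + gap * bump
  }
  list(x = x, y = y)
}
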