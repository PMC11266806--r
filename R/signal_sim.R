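# Forward simulation of the detection module: a particle transits 4 pairs of
# face-to-face electrodes wired in the two-current differential scheme
# (180-degree phase-split excitation), producing a bipolar signal with 4
# alternating lobes per frequency.

#' Electrode and acquisition configuration
#'
#' @param n_pairs Number of face-to-face electrode pairs (4 in the reference
#'   design).
#' @param pair_pitch Centre-to-centre spacing of adjacent pairs, micrometres.
#' @param sensitivity_width Spatial width (Gaussian sigma) of each pair's
#'   unimodal sensitivity lobe, micrometres. The true field profile would come
#'   from an FEM solve; a Gaussian surrogate preserves the signal properties
#'   that matter (4 alternating peaks, central symmetry).
#' @param excitation_voltage Excitation amplitude per frequency, volts.
#' @param frequencies Excitation frequencies in Hz, strictly increasing.
#' @param ta_gain Trans-impedance amplifier gain, V/A.
#' @param sample_rate Baseband sample rate per frequency, samples/s.
#' @param demod_bandwidth_fraction Lock-in low-pass bandwidth as a fraction of
#'   each carrier frequency.
#' @param pair_weights Relative coupling strength of each electrode pair, as
#'   seen from trajectory T1 (T2 sees them in reverse order). Real arrays are
#'   not perfectly uniform; the default makes pair 2 the strongest (so the
#'   second peak is the most sensitive one) and has zero alternating sum (so
#'   the differential kernel integrates to zero, the charge-balance property
#'   of a differential measurement).
#' @param gain_constant Calibration constant G collecting voltage, gain and
#'   electrode geometry: the amplitude channel is
#'   G * d^3 * |CM(f)| * kernel(x), with d in micrometres.
#' @return An object of class `electrode_config`.
#' @export
electrode_config <- function(n_pairs = 4, pair_pitch = 60,
                             sensitivity_width = 20,
                             excitation_voltage = 3.3,
                             frequencies = c(0.5e6, 1e6, 2e6),
                             ta_gain = 1e3, sample_rate = 115000,
                             demod_bandwidth_fraction = 0.01,
                             pair_weights = c(0.90, 1.00, 0.95, 0.85),
                             gain_constant = 1e-3) {
  stop_if(n_pairs < 2, "need at least 2 electrode pairs")
  stop_if(any(diff(frequencies) <= 0), "frequencies must be strictly increasing")
  stop_if(sample_rate <= 0, "sample_rate must be > 0")
  stop_if(pair_pitch <= 0 || sensitivity_width <= 0,
          "electrode geometry must be positive")
  stop_if(length(pair_weights) != n_pairs, "need one weight per electrode pair")
  stop_if(any(pair_weights <= 0), "pair_weights must be > 0")
  structure(list(n_pairs = n_pairs, pair_pitch = pair_pitch,
                 sensitivity_width = sensitivity_width,
                 excitation_voltage = excitation_voltage,
                 frequencies = frequencies, ta_gain = ta_gain,
                 sample_rate = sample_rate,
                 demod_bandwidth_fraction = demod_bandwidth_fraction,
                 pair_weights = pair_weights,
                 gain_constant = gain_constant),
            class = "electrode_config")
}

#' Noise model for simulated signals
#'
#' Additive white Gaussian noise on the amplitude channels, independent phase
#' noise, and an optional linear baseline drift. Defaults give a second-peak
#' SNR of roughly 60 for a 9-um WBC; no noise floor is printed for the
#' physical instrument, so this is a stated choice of the virtual one.
#'
#' @param amplitude_noise_sd Amplitude noise s.d., same units as the amplitude
#'   channel.
#' @param phase_noise_sd Phase noise s.d., radians.
#' @param baseline_drift Linear drift rate, amplitude units per second.
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(amplitude_noise_sd = 0.005, phase_noise_sd = 0.02,
                        baseline_drift = 0, seed = NULL) {
  stop_if(amplitude_noise_sd < 0 || phase_noise_sd < 0, "noise sds must be >= 0")
  structure(list(amplitude_noise_sd = amplitude_noise_sd,
                 phase_noise_sd = phase_noise_sd,
                 baseline_drift = baseline_drift, seed = seed),
            class = "noise_model")
}

#' A single particle transit
#'
#' @param particle A [shelled_cell()] or [bead_particle()].
#' @param trajectory `"T1"` or `"T2"`, the two symmetric equilibrium focusing
#'   trajectories of the asymmetric serpentine channel.
#' @param speed Transit speed, m/s.
#' @param start_time Event start time, seconds (metadata only).
#' @return An object of class `transit_event`.
#' @export
transit_event <- function(particle, trajectory = c("T1", "T2"), speed = 0.15,
                          start_time = 0) {
  trajectory <- match.arg(trajectory)
  stop_if(speed <= 0, "speed must be > 0")
  structure(list(particle = particle, trajectory = trajectory, speed = speed,
                 start_time = start_time),
            class = "transit_event")
}

# evaluate code with a locally-set RNG seed, restoring the global stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Differential spatial weighting kernel
#'
#' Signed sum of `n_pairs` unimodal (Gaussian) sensitivity lobes with
#' alternating signs at the pair centres, peak magnitude normalized to 1.
#' The two-current wiring makes adjacent pairs contribute with opposite sign,
#' so a transit yields a bipolar multi-lobe signal whose lobe count equals the
#' number of pairs. The trajectory-2 kernel is the point reflection of the
#' trajectory-1 kernel about the array centre (central symmetry), so the same
#' particle gives signals of equal shape and size on either trajectory.
#'
#' @param config An [electrode_config()].
#' @param trajectory `"T1"` or `"T2"`.
#' @return A list with `fn(x)` (x in micrometres from the array centre),
#'   lobe `centers` (um), `signs`, and the spatial `support` interval (um).
#' @export
differential_kernel <- function(config, trajectory = c("T1", "T2")) {
  stopifnot(inherits(config, "electrode_config"))
  trajectory <- match.arg(trajectory)
  n <- config$n_pairs
  centers <- (seq_len(n) - (n + 1) / 2) * config$pair_pitch
  signs <- (-1)^(seq_len(n) - 1)          # +,-,+,- for T1
  w <- config$pair_weights
  if (trajectory == "T2") {               # point reflection of T1: -k1(-x)
    signs <- -rev(signs)
    w <- rev(w)
  }
  sig <- config$sensitivity_width
  amps <- signs * w
  raw <- function(x) {
    out <- numeric(length(x))
    for (i in seq_len(n)) out <- out + amps[i] * exp(-(x - centers[i])^2 / (2 * sig^2))
    out
  }
  support <- range(centers) + c(-5, 5) * sig
  # peak magnitude to machine precision: coarse grid argmax, then refine
  grid <- seq(support[1], support[2], length.out = 2048)
  vg <- abs(raw(grid))
  i0 <- which.max(vg)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  norm <- stats::optimize(function(x) abs(raw(x)), c(lo, hi),
                          maximum = TRUE, tol = 1e-12)$objective
  list(fn = function(x) raw(x) / norm, centers = centers, signs = signs,
       weights = w, support = support, trajectory = trajectory)
}

new_event_signal <- function(amplitude, phase, sample_rate, frequencies,
                             meta = list()) {
  stopifnot(nrow(amplitude) == nrow(phase), ncol(amplitude) == ncol(phase))
  structure(list(amplitude = amplitude, phase = phase,
                 sample_rate = sample_rate, frequencies = frequencies,
                 meta = meta),
            class = "event_signal")
}

#' @export
print.event_signal <- function(x, ...) {
  cat(sprintf("<event_signal: %d samples x %d frequencies @ %g Sa/s%s>\n",
              nrow(x$amplitude), length(x$frequencies), x$sample_rate,
              if (!is.null(x$meta$label)) paste0(", ", x$meta$label) else ""))
  invisible(x)
}

#' Six-channel matrix view of an event signal
#'
#' Channel order (the container convention used throughout):
#' amplitude at each frequency in increasing order, then phase at each
#' frequency in increasing order. With the default three frequencies this is
#' `amp_0.5MHz, amp_1MHz, amp_2MHz, phase_0.5MHz, phase_1MHz, phase_2MHz`.
#'
#' @param sig An `event_signal`.
#' @return Numeric matrix, samples x (2 * n_frequencies).
#' @export
signal_channels <- function(sig) {
  stopifnot(inherits(sig, "event_signal"))
  m <- cbind(sig$amplitude, sig$phase)
  colnames(m) <- c(paste0("amp_", sig$frequencies),
                   paste0("phase_", sig$frequencies))
  m
}

#' Simulate one transit event (baseband model)
#'
#' Amplitude channel at frequency f:
#' `G * d^3 * |CM(f)| * kernel(position(t)) + noise (+ drift)`; phase channel:
#' `Arg(CM(f)) + phase noise` over the event support. Deterministic under a
#' fixed `noise$seed`.
#'
#' @param event A [transit_event()].
#' @param config An [electrode_config()].
#' @param medium A [medium()].
#' @param noise A [noise_model()].
#' @return An `event_signal` whose traces span the kernel support.
#' @export
simulate_event <- function(event, config = electrode_config(),
                           medium = default_medium(),
                           noise = noise_model(0, 0)) {
  stopifnot(inherits(event, "transit_event"), inherits(config, "electrode_config"))
  ker <- differential_kernel(config, event$trajectory)
  span_um <- diff(ker$support)
  duration <- span_um * 1e-6 / event$speed
  n <- floor(duration * config$sample_rate)
  stop_if(n < 20,
    "event too fast to resolve: %d samples at %g Sa/s (need >= 20)",
    n, config$sample_rate)
  # grid centred on the array so that sample i and sample n+1-i sit at
  # exactly opposite positions: central symmetry then holds to machine
  # precision, not just up to one sample of truncation
  tt <- (seq_len(n) - (n + 1) / 2) / config$sample_rate
  x <- event$speed * tt * 1e6  # position, um, 0 = array centre
  k <- ker$fn(x)
  d <- event$particle$diameter
  cm <- clausius_mossotti(event$particle, medium, config$frequencies)
  nf <- length(config$frequencies)
  base <- config$gain_constant * d^3
  amp <- outer(k, abs(cm)) * base
  ph <- matrix(Arg(cm), nrow = n, ncol = nf, byrow = TRUE)
  with_seed(noise$seed, {
    if (noise$amplitude_noise_sd > 0)
      amp <- amp + matrix(rnorm(n * nf, sd = noise$amplitude_noise_sd), n, nf)
    if (noise$baseline_drift != 0)
      amp <- amp + noise$baseline_drift * tt
    if (noise$phase_noise_sd > 0)
      ph <- ph + matrix(rnorm(n * nf, sd = noise$phase_noise_sd), n, nf)
  })
  new_event_signal(amp, ph, config$sample_rate, config$frequencies,
                   meta = list(label = event$particle$label,
                               subtype = event$particle$subtype,
                               trajectory = event$trajectory,
                               diameter = d, speed = event$speed,
                               start_time = event$start_time,
                               seed = noise$seed))
}

# PBS, the default suspending medium
default_medium <- function() medium(conductivity = 1.6, relative_permittivity = 78)
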