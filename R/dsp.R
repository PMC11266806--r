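# Impedance data processing: detrend/filter, event detection, peak
# extraction, electrical features, size calibration, detection-limit and
# correlation utilities.

#' Build a multi-channel stream object
#'
#' A stream is a samples x 6 channel matrix (see [signal_channels()] for the
#' channel order) plus acquisition metadata. Streams are what the detector
#' consumes; single simulated events can be wrapped directly.
#'
#' @param channels Numeric matrix, samples x (2 * n_frequencies).
#' @param sample_rate Samples per second.
#' @param frequencies Excitation frequencies, Hz.
#' @return An object of class `signal_stream`.
#' @export
signal_stream <- function(channels, sample_rate, frequencies) {
  channels <- as.matrix(channels)
  stop_if(ncol(channels) != 2 * length(frequencies),
          "stream needs 2 channels (amplitude, phase) per frequency")
  structure(list(channels = channels, sample_rate = sample_rate,
                 frequencies = frequencies),
            class = "signal_stream")
}

#' @rdname signal_stream
#' @param sig An `event_signal` to convert.
#' @export
as_stream <- function(sig) {
  stopifnot(inherits(sig, "event_signal"))
  signal_stream(signal_channels(sig), sig$sample_rate, sig$frequencies)
}

#' Detrend and low-pass filter a stream
#'
#' Removes the slow baseline from the amplitude channels by moving-median
#' subtraction (the median over a window much longer than an event transit is
#' insensitive to the events themselves) and then smooths every channel with
#' a zero-phase symmetric FIR low-pass, so peak times are not shifted. Phase
#' channels are smoothed but not baseline-subtracted: phase is referenced to
#' the lock-in and its event value is read at the peak sample.
#'
#' @param stream A [signal_stream()].
#' @param baseline_window Moving-median window, samples (odd; must exceed the
#'   event duration).
#' @param cutoff Low-pass cutoff as a fraction of Nyquist.
#' @return A cleaned `signal_stream`.
#' @export
detrend_and_filter <- function(stream, baseline_window = 1001, cutoff = 0.1) {
  stopifnot(inherits(stream, "signal_stream"))
  stop_if(baseline_window < 3, "baseline_window must be >= 3 samples")
  stop_if(cutoff <= 0 || cutoff >= 1, "cutoff must be in (0, 1) of Nyquist")
  if (baseline_window %% 2 == 0) baseline_window <- baseline_window + 1
  ch <- stream$channels
  nf <- length(stream$frequencies)
  n <- nrow(ch)
  bw <- min(baseline_window, if (n %% 2 == 1) n else n - 1)
  for (j in seq_len(nf))  # amplitude channels only
    ch[, j] <- ch[, j] - stats::runmed(ch[, j], bw, endrule = "median")
  h <- fir_lowpass(cutoff * stream$sample_rate / 2, stream$sample_rate,
                   transition_hz = cutoff * stream$sample_rate / 4)
  if (length(h) < n) for (j in seq_len(ncol(ch))) ch[, j] <- fir_apply(ch[, j], h)
  signal_stream(ch, stream$sample_rate, stream$frequencies)
}

#' Detect candidate events in a cleaned stream
#'
#' Thresholds the reference channel (0.5 MHz amplitude, the largest cell
#' response at low frequency) at `k` times a robust noise scale (median
#' absolute deviation), merges excursions separated by less than a refractory
#' gap, and returns fragments with context margins.
#'
#' @param stream A cleaned [signal_stream()].
#' @param k Threshold multiplier on the MAD-based noise scale (>= 3).
#' @param refractory_gap Excursions closer than this (samples) are merged.
#' @param margin Context samples appended on both sides of each excursion.
#' @param min_width Minimum number of above-threshold samples per excursion;
#'   isolated single-sample noise spikes are not events.
#' @return A list of fragments; each is a `signal_stream` with
#'   `start_index` / `end_index` attributes into the parent stream.
#' @export
detect_events <- function(stream, k = 5, refractory_gap = 100, margin = 40,
                          min_width = 3) {
  stopifnot(inherits(stream, "signal_stream"))
  stop_if(k < 3, "threshold multiplier k must be >= 3")
  ref <- stream$channels[, 1]
  stop_if(length(ref) == 0, "empty stream")
  scale <- stats::mad(ref)
  if (scale == 0) scale <- 1e-12 * max(1, max(abs(ref)))
  hot <- abs(ref) > k * scale
  if (!any(hot)) return(list())
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- cbind(starts[r$values], ends[r$values])
  # merge excursions separated by less than the refractory gap
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) for (i in 2:nrow(seg)) {
    if (seg[i, 1] - merged[nrow(merged), 2] <= refractory_gap)
      merged[nrow(merged), 2] <- seg[i, 2]
    else merged <- rbind(merged, seg[i, ])
  }
  wide <- vapply(seq_len(nrow(merged)), function(i)
    sum(hot[merged[i, 1]:merged[i, 2]]) >= min_width, logical(1))
  merged <- merged[wide, , drop = FALSE]
  n <- length(ref)
  lapply(seq_len(nrow(merged)), function(i) {
    lo <- max(1, merged[i, 1] - margin)
    hi <- min(n, merged[i, 2] + margin)
    frag <- signal_stream(stream$channels[lo:hi, , drop = FALSE],
                          stream$sample_rate, stream$frequencies)
    attr(frag, "start_index") <- lo
    attr(frag, "end_index") <- hi
    frag
  })
}

# local extrema of v with |v| above frac * max|v|; consecutive extrema of the
# same sign (noise ripple on one lobe) are collapsed to the dominant one
local_extrema <- function(v, frac = 0.2) {
  n <- length(v)
  if (n < 3) return(integer())
  d <- diff(v)
  s <- sign(d)
  s[s == 0] <- 1
  idx <- which(diff(s) != 0) + 1
  idx <- idx[abs(v[idx]) > frac * max(abs(v))]
  if (length(idx) < 2) return(idx)
  sgn <- sign(v[idx])
  run <- cumsum(c(1, diff(sgn) != 0))
  as.integer(vapply(split(idx, run),
                    function(i) i[which.max(abs(v[i]))], numeric(1)))
}

#' Extract the four alternating peaks of a fragment
#'
#' Finds the 4 dominant sign-alternating extrema per frequency. Fragments not
#' exhibiting 4 alternating extrema on the reference channel (coincident
#' cells, clipped events, noise triggers) are rejected with a reason, not
#' silently dropped. The transit trajectory is inferred from the peak
#' magnitude pattern (the electrode-pair coupling weights are point-reflected
#' between the two focusing trajectories), and peak order is canonicalized
#' (reversed and sign-flipped for T2) so that the "second peak" refers to the
#' same physical electrode pair for both trajectories.
#'
#' @param fragment A fragment from [detect_events()] (a `signal_stream`).
#' @param min_prominence Extrema below this fraction of the channel maximum
#'   are ignored.
#' @return An object of class `peak_set`: signed canonical `amplitude` and
#'   `phase` (4 x n_frequencies), original sample `index`, inferred
#'   `trajectory`, and `ok`/`reason` flags.
#' @export
extract_peaks <- function(fragment, min_prominence = 0.2) {
  stopifnot(inherits(fragment, "signal_stream"))
  nf <- length(fragment$frequencies)
  ch <- fragment$channels
  reject <- function(reason)
    structure(list(ok = FALSE, reason = reason,
                   trajectory = NA_character_), class = "peak_set")
  # locate the 4 extrema on the reference channel
  ref_idx <- local_extrema(ch[, 1], min_prominence)
  if (length(ref_idx) > 4)  # keep the 4 dominant, restore time order
    ref_idx <- sort(ref_idx[order(-abs(ch[ref_idx, 1]))][1:4])
  if (length(ref_idx) != 4) return(reject("not 4 extrema"))
  signs <- sign(ch[ref_idx, 1])
  if (any(signs[-1] * signs[-4] != -1)) return(reject("peaks not alternating"))
  if (signs[1] != 1) return(reject("first peak not positive"))
  amp <- sapply(seq_len(nf), function(j) ch[ref_idx, j])
  ph <- sapply(seq_len(nf), function(j) ch[ref_idx, nf + j])
  idx <- matrix(ref_idx, 4, nf)
  mags <- abs(amp[, 1])
  trajectory <- if (mags[2] >= mags[3]) "T1" else "T2"
  if (trajectory == "T2") {  # canonical order: as seen from trajectory 1
    amp <- -amp[4:1, , drop = FALSE]
    ph <- ph[4:1, , drop = FALSE]
    idx <- idx[4:1, , drop = FALSE]
  }
  structure(list(ok = TRUE, reason = NULL, amplitude = amp, phase = ph,
                 index = idx, trajectory = trajectory,
                 frequencies = fragment$frequencies),
            class = "peak_set")
}

#' Fit the electrical size calibration
#'
#' Least-squares line `diameter = a * amplitude^(1/3) + b` per frequency and
#' peak index, using beads of known diameter. The amplitude of the impedance
#' perturbation is proportional to particle volume, so amplitude^(1/3) is
#' linear in diameter.
#'
#' @param peak_sets List of accepted [extract_peaks()] results for bead events.
#' @param diameters True bead diameters, micrometres (one per peak set; at
#'   least 3 distinct sizes).
#' @return An object of class `size_calibration` with `slope`, `intercept`
#'   and `r_squared` matrices (peak x frequency).
#' @export
fit_size_calibration <- function(peak_sets, diameters) {
  ok <- vapply(peak_sets, function(p) isTRUE(p$ok), logical(1))
  peak_sets <- peak_sets[ok]
  diameters <- diameters[ok]
  stop_if(length(unique(diameters)) < 3,
          "need at least 3 distinct bead sizes (got %d)",
          length(unique(diameters)))
  nf <- length(peak_sets[[1]]$frequencies)
  slope <- intercept <- r2 <- matrix(NA_real_, 4, nf)
  for (p in 1:4) for (j in seq_len(nf)) {
    x <- vapply(peak_sets, function(s) abs(s$amplitude[p, j]), numeric(1))^(1/3)
    stop_if(stats::sd(x) == 0, "degenerate amplitudes at peak %d", p)
    fit <- stats::lm(diameters ~ x)
    slope[p, j] <- coef(fit)[2]
    intercept[p, j] <- coef(fit)[1]
    # direct R^2 (summary.lm warns on the noiseless, numerically exact fit)
    r2[p, j] <- 1 - sum(stats::residuals(fit)^2) /
      sum((diameters - mean(diameters))^2)
  }
  stop_if(any(slope <= 0), "calibration slope must be positive")
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 frequencies = peak_sets[[1]]$frequencies),
            class = "size_calibration")
}

#' Second-peak electrical features of one event
#'
#' Electrical diameter from the second-peak amplitude at the lowest frequency
#' via the bead calibration; opacities as high/low frequency amplitude
#' ratios at the second peak; OpTheta as the ratio of phases (radians) at the
#' second peak. Events whose low-frequency phase is within 1e-3 rad of zero
#' are flagged (phase ratio unstable).
#'
#' @param peaks An accepted [extract_peaks()] result.
#' @param calibration A [fit_size_calibration()] result, or `NULL` to skip
#'   diameter estimation.
#' @param peak_index Which canonical peak to read (default 2, the most
#'   sensitive and stable one).
#' @return An object of class `event_features` (also a one-row data.frame via
#'   [as.data.frame()]).
#' @export
compute_features <- function(peaks, calibration = NULL, peak_index = 2) {
  stopifnot(inherits(peaks, "peak_set"))
  stop_if(!isTRUE(peaks$ok), "cannot compute features of a rejected peak set")
  a <- abs(peaks$amplitude[peak_index, ])
  stop_if(a[1] == 0, "zero low-frequency amplitude")
  ph <- peaks$phase[peak_index, ]
  diameter <- if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "size_calibration"))
    calibration$slope[peak_index, 1] * a[1]^(1/3) +
      calibration$intercept[peak_index, 1]
  } else NA_real_
  structure(list(
    estimated_diameter = unname(diameter),
    opacity_1_05 = unname(a[2] / a[1]),
    opacity_2_05 = unname(a[3] / a[1]),
    opacity_2_1 = unname(a[3] / a[2]),
    op_theta_2_05 = unname(ph[3] / ph[1]),
    phase_unstable = abs(ph[1]) < 1e-3,
    peak_index_used = peak_index,
    amplitudes = unname(a),
    trajectory = peaks$trajectory), class = "event_features")
}

#' @export
as.data.frame.event_features <- function(x, ...) {
  data.frame(estimated_diameter = x$estimated_diameter,
             opacity_1_05 = x$opacity_1_05, opacity_2_05 = x$opacity_2_05,
             opacity_2_1 = x$opacity_2_1, op_theta_2_05 = x$op_theta_2_05,
             phase_unstable = x$phase_unstable,
             trajectory = x$trajectory)
}

#' Minimum detectable particle size
#'
#' Inverts the size calibration at the amplitude a peak must exceed to be
#' detected (`snr_threshold * noise_sd`), per peak and frequency. Monotone
#' increasing in the noise level; as noise vanishes it tends to
#' `max(intercept, 0)`.
#'
#' @param noise_sd Amplitude noise standard deviation (> 0).
#' @param calibration A [fit_size_calibration()] result.
#' @param snr_threshold Required signal-to-noise ratio (>= 1, default 3).
#' @return Matrix of minimum detectable diameters (um), peak x frequency.
#' @export
minimum_detectable_size <- function(noise_sd, calibration, snr_threshold = 3) {
  stopifnot(inherits(calibration, "size_calibration"))
  stop_if(noise_sd <= 0, "noise_sd must be > 0")
  stop_if(snr_threshold < 1, "snr_threshold must be >= 1")
  pmax(calibration$slope * (snr_threshold * noise_sd)^(1/3) +
         calibration$intercept, 0)
}

#' Resample a fragment to the fixed classifier tensor
#'
#' Linearly resamples each of the 6 channels to exactly 100 samples and
#' normalizes to unit scale. The three amplitude channels share one max-abs
#' scale (normalizing them independently would map every amplitude channel to
#' the same unit-peak lobe shape and erase the cross-frequency ratios that
#' carry the dielectric information); the phase channels are divided by their
#' fixed full scale pi. Scales are stored, so the normalization is
#' invertible; an all-zero channel maps to zero.
#'
#' @param fragment A `signal_stream` fragment of length >= 20.
#' @param n_out Output length (100 in the reference design).
#' @param label Optional class label carried with the tensor.
#' @return An object of class `fragment_tensor`: `data` (n_out x 6),
#'   per-channel `scales`, `label`.
#' @export
resample_fragment <- function(fragment, n_out = 100, label = NULL) {
  stopifnot(inherits(fragment, "signal_stream"))
  n <- nrow(fragment$channels)
  stop_if(n < 20, "fragment too short to resample (%d < 20 samples)", n)
  nf <- length(fragment$frequencies)
  xout <- seq(1, n, length.out = n_out)
  dat <- apply(fragment$channels, 2, function(v)
    stats::approx(seq_len(n), v, xout = xout)$y)
  amp_scale <- max(abs(dat[, seq_len(nf)]))
  if (amp_scale == 0) amp_scale <- 1
  scales <- c(rep(amp_scale, nf), rep(pi, nf))
  dat <- sweep(dat, 2, scales, "/")
  structure(list(data = dat, scales = scales, label = label),
            class = "fragment_tensor")
}

#' Pearson correlation matrix of event features
#'
#' @param features A data.frame of features (as from rbinding
#'   [as.data.frame.event_features()] rows) or a list of `event_features`.
#' @return Symmetric correlation matrix over the five electrical parameters,
#'   with a logical `flagged` attribute marking undefined entries (constant
#'   columns).
#' @export
feature_correlation_matrix <- function(features) {
  if (!is.data.frame(features))
    features <- do.call(rbind, lapply(features, as.data.frame))
  stop_if(nrow(features) < 3, "need at least 3 events")
  cols <- c("estimated_diameter", "opacity_1_05", "opacity_2_05",
            "opacity_2_1", "op_theta_2_05")
  cols <- intersect(cols, names(features))
  m <- as.matrix(features[, cols])
  constant <- apply(m, 2, function(v) stats::sd(v) == 0 || !all(is.finite(v)))
  cm <- suppressWarnings(stats::cor(m))
  diag(cm) <- 1
  attr(cm, "flagged") <- outer(constant, constant, "|") & row(cm) != col(cm)
  cm
}
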