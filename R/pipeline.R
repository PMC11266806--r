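# Orchestration: virtual sample -> sorting -> signal stream -> DSP ->
# classification -> sample-level counts and diagnosis flag.

#' Full-run configuration
#'
#' @param background Background population: a [population_spec()] (defaults
#'   to the reference scenario background, 20 ml of 5e5 WBC/ml).
#' @param spike_count Number of tumor cells spiked into the sample.
#' @param spike_preset Tumor preset used for spikes.
#' @param max_background Desk-scale subsample cap on the background; the
#'   factor is recorded and WBC counts are rescaled in the report.
#' @param electrode An [electrode_config()].
#' @param noise A [noise_model()].
#' @param stages Sorting-stage chain (list of [sorting_stage()]); `NULL` for
#'   the default calibrated chain.
#' @param classifier A trained `cytonet_model`, a checkpoint path, or `NULL`
#'   to fall back to the gating baseline with the given cuts.
#' @param gate_diameter_cut,gate_opacity_cut Cuts for the gating fallback.
#' @param theta_ctc,theta_total Diagnosis thresholds on predicted CTC count
#'   and total collected-cell count.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(background = NULL, spike_count = 0,
                       spike_preset = "MCF-7", max_background = 2000,
                       electrode = electrode_config(),
                       noise = noise_model(seed = 1), stages = NULL,
                       classifier = NULL, gate_diameter_cut = 13,
                       gate_opacity_cut = 0.8,
                       theta_ctc = 10, theta_total = Inf, seed = 1) {
  stop_if(theta_ctc < 0 || theta_total < 0, "thresholds must be >= 0")
  stop_if(spike_count < 0, "spike_count must be >= 0")
  background <- background %||%
    population_spec("WBC", concentration = 5e5, volume = 20)
  stages <- stages %||% default_stage_chain(seed = seed + 11)
  if (is.character(classifier)) classifier <- read_model(classifier)
  structure(list(background = background, spike_count = spike_count,
                 spike_preset = spike_preset, max_background = max_background,
                 electrode = electrode, noise = noise, stages = stages,
                 classifier = classifier,
                 gate_diameter_cut = gate_diameter_cut,
                 gate_opacity_cut = gate_opacity_cut,
                 theta_ctc = theta_ctc, theta_total = theta_total,
                 seed = seed),
            class = "run_config")
}

# bead calibration computed from the simulator itself (noiseless sweep)
default_calibration <- function(config = electrode_config(),
                                sizes = c(7, 10, 15, 20)) {
  ps <- lapply(sizes, function(d) {
    s <- simulate_event(transit_event(bead_particle(d), "T1"), config,
                        noise = noise_model(0, 0))
    extract_peaks(as_stream(s))
  })
  fit_size_calibration(ps, sizes)
}

# concatenate per-cell events into a continuous noisy stream
build_stream <- function(cells, config, noise, seed, gap = 600) {
  n <- length(cells)
  sigs <- vector("list", n)
  for (i in seq_len(n)) {
    ni <- noise
    ni$seed <- (noise$seed %||% 0 + seed + 7 * i) %% .Machine$integer.max
    sigs[[i]] <- signal_channels(
      simulate_event(transit_event(cells$particles[[i]],
                                   cells$trajectories[i]),
                     config, default_medium(), ni))
  }
  blank <- function(len, s) with_seed(s, cbind(
    matrix(rnorm(len * 3, sd = noise$amplitude_noise_sd), len, 3),
    matrix(rnorm(len * 3, sd = noise$phase_noise_sd), len, 3)))
  parts <- vector("list", 2 * n + 1)
  parts[[1]] <- blank(gap, seed + 1)
  for (i in seq_len(n)) {
    parts[[2 * i]] <- sigs[[i]]
    parts[[2 * i + 1]] <- blank(gap, seed + 2 * i + 1)
  }
  signal_stream(do.call(rbind, parts), config$sample_rate,
                config$frequencies)
}

#' Run the full virtual-instrument pipeline
#'
#' Executes all computational stages of a sample run with seeds derived
#' deterministically from the master seed: population generation, sorting
#' chain, signal-stream simulation of the product cells, detrending and
#' event detection, peak extraction and feature computation, classification
#' (CNN or gating fallback), and sample-level counting with the diagnosis
#' rule. To bound memory, product cells are streamed in chunks.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory; when given, the event
#'   container, features CSV, report JSON and a log file are written there.
#' @return An object of class `sample_report`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message("[impedcyto] ", msg)
  }
  stage_fail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)

  # 1. virtual sample
  sample <- tryCatch({
    build_spikein_scenario(cfg$background, cfg$spike_count,
                           spike_preset = cfg$spike_preset, seed = cfg$seed,
                           max_background = cfg$max_background)[[1]]
  }, error = function(e) stage_fail("sample", e))
  say("sample: %d cells (%d spiked tumor, background factor %.1f)",
      length(sample$cells), sample$spike_count, sample$background_factor)

  # 2. sorting chain
  sorted <- tryCatch(apply_stage_chain(sample$cells, cfg$stages),
                     error = function(e) stage_fail("sorting", e))
  n_in <- length(sample$cells)
  n_kept <- length(sorted$product)
  n_waste <- length(sorted$waste)
  stopifnot(n_kept + n_waste == n_in)
  say("sorting: %d in -> %d product + %d waste", n_in, n_kept, n_waste)

  # 3-5. stream simulation, DSP, features (chunked)
  calib <- default_calibration(cfg$electrode)
  chunk <- 200
  feats <- list(); tensors <- list(); frag_signals <- list()
  n_detected <- 0; rejected <- character(0)
  tryCatch({
    for (s in seq(1, max(n_kept, 1), chunk)) {
      if (n_kept == 0) break
      e <- min(n_kept, s + chunk - 1)
      sub <- structure(list(
        particles = sorted$product$particles[s:e],
        trajectories = sorted$product$trajectories[s:e],
        spec = sorted$product$spec, requested_n = e - s + 1,
        subsample_factor = 1), class = "cell_collection")
      stream <- build_stream(sub, cfg$electrode, cfg$noise,
                             seed = cfg$seed + 131 * s)
      clean <- detrend_and_filter(stream)
      frags <- detect_events(clean, k = 5)
      n_detected <- n_detected + length(frags)
      for (fr in frags) {
        pk <- extract_peaks(fr)
        if (!isTRUE(pk$ok)) { rejected <- c(rejected, pk$reason); next }
        ft <- as.data.frame(compute_features(pk, calib))
        feats[[length(feats) + 1]] <- ft
        tensors[[length(tensors) + 1]] <- resample_fragment(fr)$data
        if (length(frag_signals) < 50)  # cap the persisted container
          frag_signals[[length(frag_signals) + 1]] <- fr
      }
    }
  }, error = function(e) stage_fail("detection", e))
  n_accepted <- length(feats)
  say("detection: %d events detected, %d accepted, %d rejected",
      n_detected, n_accepted, n_detected - n_accepted)

  # 6. classification
  features <- if (n_accepted) do.call(rbind, feats) else NULL
  pred <- tryCatch({
    if (n_accepted == 0) character(0)
    else if (!is.null(cfg$classifier)) {
      x <- array(NA_real_, c(n_accepted, 100, 6))
      for (i in seq_len(n_accepted)) x[i, , ] <- tensors[[i]]
      prob <- predict_cytonet(cfg$classifier, x)
      cfg$classifier$spec$classes[max.col(prob)]
    } else gating_baseline(features, cfg$gate_diameter_cut,
                           cfg$gate_opacity_cut)
  }, error = function(e) stage_fail("classification", e))
  if (!is.null(features)) features$predicted <- pred
  n_ctc <- sum(pred == "TUMOR")
  n_wbc <- sum(pred == "WBC")
  say("classification: %d predicted WBC, %d predicted CTC", n_wbc, n_ctc)

  # 7. diagnosis
  flag <- diagnose(n_ctc, n_accepted, cfg$theta_ctc, cfg$theta_total)
  say("diagnosis: %s (theta_ctc = %g, theta_total = %g)",
      if (flag) "POSITIVE" else "negative", cfg$theta_ctc, cfg$theta_total)

  report <- structure(list(
    schema = REPORT_SCHEMA,
    software_version = as.character(utils::packageVersion("impedcyto")),
    seed = cfg$seed,
    input_cells = n_in, kept_cells = n_kept, removed_cells = n_waste,
    detected_events = n_detected, accepted_events = n_accepted,
    rejected_events = n_detected - n_accepted,
    rejection_reasons = as.list(table(rejected)),
    predicted_wbc = n_wbc, predicted_ctc = n_ctc,
    background_factor = sample$background_factor,
    predicted_wbc_rescaled = n_wbc * sample$background_factor,
    spike_count_truth = sample$spike_count,
    diagnosis_positive = flag,
    theta_ctc = cfg$theta_ctc, theta_total = cfg$theta_total,
    sorting_reports = lapply(sorted$reports, unclass),
    classifier = if (is.null(cfg$classifier)) "gating" else "cytonet"),
    class = "sample_report")

  if (!is.null(out_dir)) {
    report <- export_report(report, out_dir,
                            features = features, signals = frag_signals,
                            log_lines = log_lines)
  }
  report
}

#' Threshold diagnosis rule
#'
#' A sample is flagged positive iff the predicted CTC count reaches
#' `theta_ctc` or the total collected-cell count reaches `theta_total`
#' (disjunctive form; the thresholds are user configuration).
#'
#' @param predicted_ctc Predicted CTC count.
#' @param total_cells Total collected (accepted) cell count.
#' @param theta_ctc,theta_total Thresholds (>= 0; `Inf` disables a clause).
#' @return Logical flag.
#' @export
diagnose <- function(predicted_ctc, total_cells, theta_ctc, theta_total = Inf) {
  stop_if(theta_ctc < 0 || theta_total < 0, "thresholds must be >= 0")
  predicted_ctc >= theta_ctc || total_cells >= theta_total
}

#' Export a sample report with its side files
#'
#' Writes `report.json`, `features.csv`, an event container under `events/`
#' (first accepted fragments), and `run.log`; paths are recorded in the
#' returned report.
#'
#' @param report A `sample_report`.
#' @param out_dir Output directory (must exist or be creatable).
#' @param features Optional feature data.frame.
#' @param signals Optional list of fragments for the event container.
#' @param log_lines Optional character vector for the log file.
#' @return The report with a `paths` field, invisibly.
#' @export
export_report <- function(report, out_dir, features = NULL, signals = NULL,
                          log_lines = character(0)) {
  stopifnot(inherits(report, "sample_report"))
  ok <- tryCatch({ dir.create(out_dir, recursive = TRUE, showWarnings = FALSE); TRUE },
                 error = function(e) FALSE)
  stop_if(!ok || !dir.exists(out_dir), "cannot create output directory '%s'", out_dir)
  paths <- list(report = file.path(out_dir, "report.json"),
                log = file.path(out_dir, "run.log"))
  if (!is.null(features)) {
    paths$features <- file.path(out_dir, "features.csv")
    write_features(features, paths$features)
  }
  if (length(signals)) {
    paths$events <- file.path(out_dir, "events")
    # fragments carry no per-event meta; wrap as bare signals
    write_event_container(lapply(signals, function(fr) {
      nf <- length(fr$frequencies)
      new_event_signal(fr$channels[, seq_len(nf), drop = FALSE],
                       fr$channels[, nf + seq_len(nf), drop = FALSE],
                       fr$sample_rate, fr$frequencies)
    }), paths$events)
  }
  writeLines(log_lines, paths$log)
  report$paths <- lapply(paths, normalizePath, mustWork = FALSE)
  write_report(report, paths$report)
  invisible(report)
}
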