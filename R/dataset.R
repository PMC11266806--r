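# Bridge between the virtual lab and the classifier: turn cell collections
# into labeled fragment tensors.

#' Simulate a labeled fragment dataset from cell collections
#'
#' The fast path used to build training data: each cell is simulated as one
#' isolated transit ([simulate_event()]) on its assigned trajectory with
#' fresh noise, and the whole event trace is resampled directly to the
#' 100 x 6 tensor ([resample_fragment()]). This bypasses stream-level
#' detection (every fragment is known to contain exactly one event); the
#' full detection route is exercised by [run_pipeline()].
#'
#' @param cells A `cell_collection` (see [generate_population()]), or a list
#'   of them (concatenated).
#' @param config An [electrode_config()].
#' @param noise A [noise_model()]; its `seed` is combined with the event
#'   index so every event gets an independent, reproducible noise draw.
#' @param medium A [medium()].
#' @param n_out Samples per output fragment.
#' @return List with `x` (array `[N, n_out, 6]`), `y` (labels), `subtype`,
#'   `trajectory`, `diameter`.
#' @export
fragment_dataset <- function(cells, config = electrode_config(),
                             noise = noise_model(seed = 1),
                             medium = default_medium(), n_out = 100) {
  if (inherits(cells, "cell_collection")) cells <- list(cells)
  particles <- do.call(c, lapply(cells, `[[`, "particles"))
  traj <- do.call(c, lapply(cells, `[[`, "trajectories"))
  N <- length(particles)
  stop_if(N == 0, "empty cell collection")
  base_seed <- noise$seed %||% 0
  x <- array(NA_real_, c(N, n_out, 6))
  y <- character(N); subtype <- character(N); diam <- numeric(N)
  for (i in seq_len(N)) {
    ni <- noise
    ni$seed <- (base_seed + i) %% .Machine$integer.max
    sig <- simulate_event(transit_event(particles[[i]], traj[i]),
                          config, medium, ni)
    x[i, , ] <- resample_fragment(as_stream(sig), n_out = n_out)$data
    y[i] <- particles[[i]]$label
    subtype[i] <- particles[[i]]$subtype
    diam[i] <- particles[[i]]$diameter
  }
  list(x = x, y = y, subtype = subtype, trajectory = traj, diameter = diam)
}

#' Reference two-class training run
#'
#' The package's standard benchmark: a 1:1 WBC:tumor synthetic dataset at
#' default noise, processed to fragment tensors, stratified 7:3 split and
#' CNN training with a fixed seed. Returns the fit plus the held-out
#' confusion matrix. This is the scaled-down, fully synthetic counterpart of
#' training on measured cell-line datasets.
#'
#' @param n_per_class Events per class.
#' @param seed Master seed (populations, noise, split, initialization).
#' @param tumor_preset Which tumor line preset to mix with WBCs.
#' @param epochs Epoch cap (training stops earlier on loss plateau).
#' @param config,noise Acquisition and noise settings.
#' @return List: `fit` (see [train_cytonet()]), `cm` (held-out
#'   [confusion_matrix()]), `data` (the dataset).
#' @export
reference_training_run <- function(n_per_class = 10000, seed = 1,
                                   tumor_preset = "MCF-7", epochs = 100,
                                   config = electrode_config(),
                                   noise = NULL) {
  noise <- noise %||% noise_model(seed = seed + 2)
  wbc <- generate_population(population_spec("WBC", n = n_per_class),
                             seed = seed)
  tum <- generate_population(population_spec(tumor_preset, n = n_per_class),
                             seed = seed + 1)
  ds <- fragment_dataset(list(wbc, tum), config = config, noise = noise)
  cfg <- training_config(seed = seed, epochs = epochs, patience = 5)
  fit <- train_cytonet(build_model(seed = seed), ds$x, ds$y, cfg)
  cm <- evaluate_cytonet(fit$model, ds$x[fit$split$test, , , drop = FALSE],
                         ds$y[fit$split$test])
  list(fit = fit, cm = cm, data = ds)
}
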