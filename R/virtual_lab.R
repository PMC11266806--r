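# Synthetic-sample generator and phenomenological microfluidics: builds
# heterogeneous cell/bead populations, emulates the inertial
# separation/concentration stages as size-dependent stochastic capture, and
# constructs rare-cell spike-in scenarios.

#' Population specification
#'
#' Describes one virtual cell or bead population: a dielectric preset, a
#' truncated-normal diameter distribution, trajectory assignment
#' probabilities, and either a direct count or a concentration x volume.
#'
#' @param preset Material preset name (see [material_table()]).
#' @param n Number of cells, or `NULL` to use `concentration * volume`.
#' @param concentration Cells per ml (used with `volume` when `n` is `NULL`).
#' @param volume Sample volume, ml.
#' @param diameter_mean,diameter_sd Diameter distribution, um; defaults come
#'   from the preset table (WBC 9 +/- 1.5 um, tumor lines 17-18 +/- 2.5 um).
#' @param truncation Length-2 diameter bounds, um; default keeps samples
#'   inside the physical (1, 50) um range.
#' @param trajectory_prob Probability of assignment to the two focusing
#'   trajectories (sums to 1).
#' @param dielectric_cv Lognormal coefficient of variation applied per cell
#'   to membrane permittivity and cytoplasm conductivity (cell-to-cell
#'   dielectric heterogeneity; 0 disables it; ignored for beads).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(preset, n = NULL, concentration = NULL,
                            volume = NULL, diameter_mean = NULL,
                            diameter_sd = NULL, truncation = NULL,
                            trajectory_prob = c(0.5, 0.5),
                            dielectric_cv = 0.03) {
  row <- preset_row(preset)
  stop_if(row$kind == "medium", "cannot build a population of medium '%s'", preset)
  diameter_mean <- diameter_mean %||% row$diameter_um
  diameter_sd <- diameter_sd %||% (if (is.na(row$diameter_sd_um)) 0 else row$diameter_sd_um)
  truncation <- truncation %||%
    c(max(1.01, diameter_mean - 4 * diameter_sd),
      min(49.9, diameter_mean + 4 * diameter_sd))
  stop_if(diameter_sd < 0, "diameter_sd must be >= 0")
  stop_if(truncation[1] >= truncation[2] && diameter_sd > 0,
          "impossible truncation interval")
  stop_if(truncation[1] <= 0, "truncation must keep diameter > 0")
  stop_if(abs(sum(trajectory_prob) - 1) > 1e-9, "trajectory_prob must sum to 1")
  if (is.null(n)) {
    stop_if(is.null(concentration) || is.null(volume),
            "give either n or concentration + volume")
    n <- round(concentration * volume)
  }
  stop_if(n < 0, "population size must be >= 0")
  structure(list(preset = preset, n = n, concentration = concentration,
                 volume = volume, diameter_mean = diameter_mean,
                 diameter_sd = diameter_sd, truncation = truncation,
                 trajectory_prob = trajectory_prob,
                 dielectric_cv = dielectric_cv, kind = row$kind,
                 label = row$label),
            class = "population_spec")
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
}

#' Generate a virtual population
#'
#' Samples diameters from the truncated normal, attaches (jittered)
#' dielectric presets, and assigns focusing trajectories. Deterministic under
#' `seed`. Very large requests (clinical backgrounds reach 1e7 cells) can be
#' subsampled; the scale factor is recorded so downstream counts can be
#' rescaled.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @param max_cells Subsample cap; `Inf` disables subsampling.
#' @return An object of class `cell_collection`: lists `particles`,
#'   `trajectories`, plus `requested_n` and `subsample_factor`
#'   (= requested / realized).
#' @export
generate_population <- function(spec, seed = 1, max_cells = Inf) {
  stopifnot(inherits(spec, "population_spec"))
  n_req <- spec$n
  n <- min(n_req, max_cells)
  with_seed(seed, {
    d <- rtruncnorm(n, spec$diameter_mean, spec$diameter_sd,
                    spec$truncation[1], spec$truncation[2])
    traj <- sample(c("T1", "T2"), n, replace = TRUE,
                   prob = spec$trajectory_prob)
    particles <- if (spec$kind == "bead") {
      lapply(d, function(di) cell_preset(spec$preset, diameter = di))
    } else {
      cv <- spec$dielectric_cv
      jit <- if (cv > 0) {
        sdl <- sqrt(log(1 + cv^2))
        matrix(exp(rnorm(2 * n, -sdl^2 / 2, sdl)), n, 2)
      } else matrix(1, n, 2)
      lapply(seq_len(n), function(i) {
        cell <- cell_preset(spec$preset, diameter = d[i])
        cell$membrane_relative_permittivity <-
          max(1, cell$membrane_relative_permittivity * jit[i, 1])
        cell$cytoplasm_conductivity <- cell$cytoplasm_conductivity * jit[i, 2]
        cell
      })
    }
    structure(list(particles = particles, trajectories = traj,
                   spec = spec, requested_n = n_req,
                   subsample_factor = if (n > 0) n_req / n else 1),
              class = "cell_collection")
  })
}

#' Combine cell collections
#'
#' @param ... `cell_collection` objects.
#' @return One merged `cell_collection` (subsample factors must agree).
#' @export
combine_collections <- function(...) {
  colls <- list(...)
  structure(list(
    particles = do.call(c, lapply(colls, `[[`, "particles")),
    trajectories = do.call(c, lapply(colls, `[[`, "trajectories")),
    spec = lapply(colls, `[[`, "spec"),
    requested_n = sum(vapply(colls, `[[`, numeric(1), "requested_n")),
    subsample_factor = colls[[1]]$subsample_factor),
    class = "cell_collection")
}

#' @export
length.cell_collection <- function(x) length(x$particles)

#' Phenomenological sorting stage
#'
#' The inertial physics of the spiral/serpentine channels (lift and Dean
#' drag) is not simulated; a stage is a calibrated logistic capture curve in
#' diameter: `p(keep) = floor + (ceiling - floor) / (1 + exp(-steepness *
#' (d - midpoint)))`. Defaults are calibrated so that, on the default WBC and
#' tumor presets, the stage depletes ~98% of WBCs and recovers ~90% of tumor
#' cells - fitted stand-ins for the measured stage efficiencies, not
#' hydrodynamic predictions.
#'
#' @param name Stage name ("separation", "concentration1", "concentration2").
#' @param midpoint Diameter at half-maximum capture, um.
#' @param steepness Logistic steepness, 1/um.
#' @param floor,ceiling Capture probability bounds, 0 <= floor <= ceiling <= 1.
#' @param seed Integer seed for the Bernoulli keep decisions.
#' @return An object of class `sorting_stage`.
#' @export
sorting_stage <- function(name = "separation", midpoint = 12.6,
                          steepness = 1.9, floor = 0, ceiling = 0.92,
                          seed = 1) {
  stop_if(floor < 0 || ceiling > 1 || floor > ceiling,
          "need 0 <= floor <= ceiling <= 1")
  stop_if(steepness <= 0, "steepness must be > 0")
  structure(list(name = name, midpoint = midpoint, steepness = steepness,
                 floor = floor, ceiling = ceiling, seed = seed),
            class = "sorting_stage")
}

#' Default separation/concentration stage chain
#'
#' The spiral separation stage does the WBC depletion; the two serpentine
#' concentration stages mostly pass cells through with a mild small-size
#' loss, so that per-stage tumor recovery stays ~90% or better and the
#' integrated chain reproduces the qualitative behavior of the reference
#' device (most WBCs to waste, most tumor cells kept).
#'
#' @param seed Base seed; stages use seed, seed+1, seed+2.
#' @return List of three [sorting_stage()] objects.
#' @export
default_stage_chain <- function(seed = 1) {
  list(sorting_stage("separation", seed = seed),
       sorting_stage("concentration1", midpoint = 6, steepness = 1.2,
                     ceiling = 0.97, seed = seed + 1),
       sorting_stage("concentration2", midpoint = 6, steepness = 1.2,
                     ceiling = 0.97, seed = seed + 2))
}

#' Apply a sorting stage to a collection
#'
#' Independent Bernoulli keep-decision per cell with probability given by the
#' stage's logistic capture curve; the report is computed on the realized
#' outcome.
#'
#' @param cells A `cell_collection`.
#' @param stage A [sorting_stage()].
#' @return List with `product` and `waste` (both `cell_collection`) and
#'   `report` (class `sorting_report`): per-label recovery efficiency RE,
#'   depletion efficiency DE = 1 - RE, and product purity per label.
#' @export
apply_sorting <- function(cells, stage) {
  stopifnot(inherits(cells, "cell_collection"), inherits(stage, "sorting_stage"))
  d <- vapply(cells$particles, `[[`, numeric(1), "diameter")
  p <- stage$floor + (stage$ceiling - stage$floor) /
    (1 + exp(-stage$steepness * (d - stage$midpoint)))
  keep <- with_seed(stage$seed, runif(length(d)) < p)
  subset_coll <- function(i) structure(
    list(particles = cells$particles[i], trajectories = cells$trajectories[i],
         spec = cells$spec, requested_n = sum(i),
         subsample_factor = cells$subsample_factor),
    class = "cell_collection")
  labels <- vapply(cells$particles, `[[`, character(1), "label")
  re <- tapply(keep, labels, mean)
  kept_labels <- labels[keep]
  purity <- if (length(kept_labels))
    table(factor(kept_labels, levels = unique(labels))) / length(kept_labels)
  else setNames(rep(NA_real_, length(unique(labels))), unique(labels))
  report <- structure(list(stage = stage$name,
                           recovery_efficiency = as.list(re),
                           depletion_efficiency = as.list(1 - re),
                           purity = as.list(as.numeric(purity) |>
                                              setNames(names(purity))),
                           n_in = length(d), n_kept = sum(keep)),
                      class = "sorting_report")
  list(product = subset_coll(keep), waste = subset_coll(!keep),
       report = report)
}

#' Run a collection through a chain of stages
#'
#' @param cells A `cell_collection`.
#' @param stages List of [sorting_stage()] objects.
#' @return List with final `product`, combined `waste`, and per-stage
#'   `reports`.
#' @export
apply_stage_chain <- function(cells, stages) {
  reports <- list()
  waste <- NULL
  cur <- cells
  for (st in stages) {
    out <- apply_sorting(cur, st)
    reports[[st$name]] <- out$report
    waste <- if (is.null(waste)) out$waste
             else combine_collections(waste, out$waste)
    cur <- out$product
  }
  list(product = cur, waste = waste, reports = reports)
}

#' Build a rare-cell spike-in scenario
#'
#' A high-concentration WBC background (the reference scenario: 20 ml at
#' 5e5 WBC/ml) spiked with known counts of tumor cells. Ground truth is the
#' generated label of each cell; the background may be subsampled for desk
#' scale with the factor recorded.
#'
#' @param background A [population_spec()] for the background (WBC) cells.
#' @param spike_counts Integer vector of tumor spike counts (one sample per
#'   entry).
#' @param spike_preset Tumor preset name for the spikes.
#' @param seed Integer seed.
#' @param max_background Subsample cap for the background population.
#' @return List of samples; each has `cells` (a `cell_collection` of
#'   background + spikes), `spike_count` (ground truth, at full scale) and
#'   `background_factor` (background subsample factor).
#' @export
build_spikein_scenario <- function(background, spike_counts,
                                   spike_preset = "MCF-7", seed = 1,
                                   max_background = 20000) {
  stop_if(any(spike_counts < 0), "spike counts must be >= 0")
  lapply(seq_along(spike_counts), function(i) {
    bg <- generate_population(background, seed = seed + 97 * i,
                              max_cells = max_background)
    sc <- spike_counts[i]
    cells <- if (sc > 0) {
      # spikes are exact counts, never subsampled
      spike <- generate_population(
        population_spec(spike_preset, n = sc), seed = seed + 97 * i + 31)
      combine_collections(bg, spike)
    } else bg
    list(cells = cells, spike_count = sc,
         background_factor = bg$subsample_factor)
  })
}
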