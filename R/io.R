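# Text-based persistence: event container (directory of delimited text),
# features table, sample report, model checkpoint. All formats carry schema
# versions and round-trip through their matching readers.

EVENT_SCHEMA <- "impedcyto-events/1"
FEATURE_SCHEMA <- "impedcyto-features/1"
REPORT_SCHEMA <- "impedcyto-report/1"
MODEL_SCHEMA <- "impedcyto-model/1"

#' Write an event container
#'
#' The event container is a documented directory of delimited text files:
#' `manifest.json` (schema version, sample rate, frequencies, channel
#' names), `channels.csv` (long table: `event_id`, `sample`, six channel
#' columns) and `events.csv` (per-event metadata: label, subtype,
#' trajectory, true diameter, seed).
#'
#' @param signals List of `event_signal` objects (or `signal_stream`
#'   fragments; metadata columns are then NA).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_event_container <- function(signals, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stop_if(length(signals) == 0, "no events to write")
  first <- signals[[1]]
  chan_names <- c(paste0("amp_", first$frequencies),
                  paste0("phase_", first$frequencies))
  rows <- lapply(seq_along(signals), function(i) {
    s <- signals[[i]]
    ch <- if (inherits(s, "event_signal")) signal_channels(s) else s$channels
    data.frame(event_id = i, sample = seq_len(nrow(ch)),
               as.data.frame(ch) |> setNames(chan_names))
  })
  write.csv(do.call(rbind, rows), file.path(dir, "channels.csv"),
            row.names = FALSE)
  meta <- do.call(rbind, lapply(seq_along(signals), function(i) {
    m <- signals[[i]]$meta %||% list()
    data.frame(event_id = i,
               label = m$label %||% NA_character_,
               subtype = m$subtype %||% NA_character_,
               trajectory = m$trajectory %||% NA_character_,
               diameter = m$diameter %||% NA_real_,
               seed = m$seed %||% NA_integer_)
  }))
  write.csv(meta, file.path(dir, "events.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(schema = EVENT_SCHEMA, sample_rate = first$sample_rate,
         frequencies = first$frequencies, n_events = length(signals),
         channels = chan_names),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an event container
#'
#' @param dir Container directory written by [write_event_container()].
#' @return List of `event_signal` objects.
#' @export
read_event_container <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  stop_if(!file.exists(mf_path), "no event container at '%s'", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  stop_if(!identical(mf$schema, EVENT_SCHEMA),
          "unsupported event container schema '%s' (expected '%s')",
          mf$schema %||% "<none>", EVENT_SCHEMA)
  ch <- read.csv(file.path(dir, "channels.csv"))
  meta <- read.csv(file.path(dir, "events.csv"))
  nf <- length(mf$frequencies)
  lapply(seq_len(mf$n_events), function(i) {
    sub <- as.matrix(ch[ch$event_id == i, 2 + seq_len(2 * nf)])
    m <- meta[meta$event_id == i, ]
    new_event_signal(sub[, seq_len(nf), drop = FALSE],
                     sub[, nf + seq_len(nf), drop = FALSE],
                     mf$sample_rate, mf$frequencies,
                     meta = list(label = m$label, subtype = m$subtype,
                                 trajectory = m$trajectory,
                                 diameter = m$diameter, seed = m$seed))
  })
}

#' Write / read the per-event feature table
#'
#' Plain CSV with documented, versioned columns: `schema`,
#' `estimated_diameter` (um), the three opacity ratios, `op_theta_2_05`,
#' `phase_unstable`, `trajectory`, and any extra columns present (e.g.
#' predicted label).
#'
#' @param features Feature data.frame.
#' @param path Output CSV path.
#' @return `path` invisibly ([write_features()]); a data.frame
#'   ([read_features()]).
#' @export
write_features <- function(features, path) {
  stop_if(!dir.exists(dirname(path)), "no such directory: '%s'", dirname(path))
  features$schema <- FEATURE_SCHEMA
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  f <- read.csv(path)
  stop_if(!all(f$schema == FEATURE_SCHEMA),
          "unsupported feature schema (expected '%s')", FEATURE_SCHEMA)
  f$schema <- NULL
  f
}

#' Write / read a sample report
#'
#' Schema-versioned JSON holding the sample-level counts, the diagnosis
#' flag, per-stage sorting reports and the seeds used. Timestamps are
#' deliberately excluded so identical runs are byte-identical.
#'
#' @param report A `sample_report` (see [run_pipeline()]).
#' @param path Output JSON path.
#' @return `path` invisibly ([write_report()]); a `sample_report`
#'   ([read_report()]).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "sample_report"))
  stop_if(!dir.exists(dirname(path)), "no such directory: '%s'", dirname(path))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  stop_if(!file.exists(path), "no such file: '%s'", path)
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  stop_if(!identical(r$schema, REPORT_SCHEMA),
          "unsupported report schema '%s' (expected '%s')",
          r$schema %||% "<none>", REPORT_SCHEMA)
  structure(r, class = "sample_report")
}

#' Write / read a model checkpoint
#'
#' JSON checkpoint embedding the model spec, all parameters at full
#' precision, and the data-schema version.
#'
#' @param model A `cytonet_model`.
#' @param path Output JSON path.
#' @return `path` invisibly ([write_model()]); a `cytonet_model`
#'   ([read_model()]).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cytonet_model"))
  pay <- list(schema = MODEL_SCHEMA,
              spec = unclass(model$spec), seed = model$seed,
              par = lapply(model$par, function(p)
                if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
                else list(dim = NULL, data = as.vector(p))))
  jsonlite::write_json(pay, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  stop_if(!file.exists(path), "no such file: '%s'", path)
  pay <- jsonlite::read_json(path, simplifyVector = TRUE)
  stop_if(!identical(pay$schema, MODEL_SCHEMA),
          "unsupported model schema '%s' (expected '%s')",
          pay$schema %||% "<none>", MODEL_SCHEMA)
  spec <- pay$spec
  spec$filters <- as.numeric(spec$filters)
  spec <- do.call(model_spec, spec[c("input_len", "n_channels", "filters",
                                     "kernel_size", "attention", "reduction",
                                     "n_classes", "classes")])
  par <- lapply(pay$par, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  structure(list(spec = spec, par = par, seed = pay$seed),
            class = "cytonet_model")
}
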