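# Plain-text input/output: BIDS-style event tables, result tables, configs.

#' Write events as a BIDS-style TSV
#'
#' Columns: `onset` (s), `duration` (s), `trial_type`,
#' `is_first_post_target_standard` and, when present, `correct`.
#'
#' @param events Event table (onsets in ms).
#' @param path Output file.
#' @param stimulus_duration Stimulus duration in ms.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(events, path, stimulus_duration = 500) {
  out <- data.frame(
    onset = events$onset / 1000,
    duration = rep(stimulus_duration / 1000, nrow(events)),
    trial_type = events$position,
    is_first_post_target_standard = events$is_first_post_target_standard
  )
  if (!is.null(events$correct)) out$correct <- events$correct
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV
#'
#' @param path File written by [write_events_tsv()].
#' @return Event table with onsets in ms.
#' @export
read_events_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(
    index = seq_len(nrow(d)),
    onset = d$onset * 1000,
    position = d$trial_type,
    is_target = d$trial_type != "center",
    is_first_post_target_standard = as.logical(d$is_first_post_target_standard),
    correct = if (!is.null(d$correct)) as.logical(d$correct) else NA,
    stringsAsFactors = FALSE
  )
}

#' Write the result tables of a study to a directory
#'
#' Emits tidy TSVs: grand-average measures, jackknife scores, ANOVA tables,
#' environment contrasts (post hoc + BF), behavior scores, alignment report
#' and the trial-count ledger, plus a JSON manifest.
#'
#' @param study An `oddball_study`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study_tsv <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, name) {
    utils::write.table(d, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  w(study$grand, "grand_measures")
  w(study$scores, "jackknife_scores")
  anova_tab <- do.call(rbind, Map(function(nm, tab) {
    cbind(data.frame(measure = nm, stringsAsFactors = FALSE), tab)
  }, names(study$anova), study$anova))
  w(anova_tab, "anova")
  w(study$environment_contrasts, "environment_contrasts")
  w(study$behavior$scores, "behavior_scores")
  w(study$behavior$anova, "behavior_anova")
  w(study$alignment$cells, "alignment_cells")
  w(study$alignment$summary, "alignment_summary")
  w(study$manifest$counts, "trial_counts")
  manifest <- study$manifest
  manifest$counts <- NULL
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write / read a continuous recording as an array container
#'
#' Stores the samples as little-endian float32 (channels fastest-varying,
#' i.e. column-major channels x samples) in `<path>.bin` with a JSON
#' sidecar `<path>.json` describing channels, sampling rate, units and
#' provenance. No EDF writer is assumed in the environment; this container
#' is the documented alternative.
#'
#' @param recording An [oddball_recording()].
#' @param path Base path (without extension).
#' @param provenance Optional list stored verbatim in the sidecar (e.g.
#'   ground-truth and seed information).
#' @return Base path, invisibly.
#' @export
write_recording <- function(recording, path, provenance = NULL) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(recording$data), con, size = 4, endian = "little")
  sidecar <- list(channels = recording$channels,
                  sampling_rate = recording$srate,
                  n_samples = ncol(recording$data),
                  t0 = recording$t0,
                  units = "uV",
                  reference = recording$reference,
                  layout = "float32 little-endian, channels x samples, channel fastest",
                  provenance = provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- length(sc$channels) * sc$n_samples
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  oddball_recording(matrix(x, nrow = length(sc$channels),
                           dimnames = list(sc$channels, NULL)),
                    channels = sc$channels, srate = sc$sampling_rate,
                    t0 = sc$t0, reference = sc$reference)
}

#' Save / load a run configuration as JSON
#'
#' Uses jsonlite's class-preserving serialization so a round-tripped
#' configuration reproduces the run exactly.
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `save_config` returns the path invisibly; `load_config` the
#'   restored `run_config`.
#' @export
save_config <- function(config, path) {
  writeLines(jsonlite::serializeJSON(config, digits = 10), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}
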