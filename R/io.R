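#' Write a recording as a plain array container with a JSON sidecar
#'
#' Serializes a `pam_recording` to `<base>_signals.csv` (one column per
#' channel role, one row per sample) and `<base>_meta.json` (sampling rate,
#' attended side, event log). A plain-text interchange format for simulated
#' recordings; real acquisitions in standard biosignal containers can be
#' adapted to the same in-memory structure.
#'
#' @param rec A `pam_recording`.
#' @param base Path prefix (without extension).
#' @return `base`, invisibly.
#' @export
write_recording <- function(rec, base) {
  utils::write.csv(as.data.frame(rec$channels),
                   paste0(base, "_signals.csv"), row.names = FALSE)
  meta <- list(rate = rec$rate, attended = rec$attended, events = rec$events)
  jsonlite::write_json(meta, paste0(base, "_meta.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' Serialize a study configuration as JSON
#'
#' Writes the fully resolved configuration (all parameter blocks) next to a
#' run's outputs so every result is reproducible from the file plus the
#' package version. [read_study_config()] restores it round-trip.
#'
#' @param config A [study_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), strip))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a study configuration written by [write_study_config()]
#' @param path JSON path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$base_params$reflex_amp <- unlist(raw$base_params$reflex_amp)
  raw$base_params <- structure(raw$base_params, class = "emg_model_params")
  raw$fspec <- structure(raw$fspec, class = "filter_spec")
  if (!length(raw$n_per_cell)) raw["n_per_cell"] <- list(NULL)
  structure(raw, class = "study_config")
}

#' Write an epoch-set label table as CSV
#'
#' One row per epoch with the design-cell labels and screening columns
#' (`snr_db`, `retained`, `selected` where present).
#'
#' @param es An `epoch_set`.
#' @param path Output CSV path.
#' @param participant Optional participant id column.
#' @return `path`, invisibly.
#' @export
write_epoch_labels <- function(es, path, participant = NA) {
  df <- cbind(participant = participant, es$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param base Path prefix used at write time.
#' @return A `pam_recording`.
#' @export
read_recording <- function(base) {
  ch <- as.matrix(utils::read.csv(paste0(base, "_signals.csv")))
  meta <- jsonlite::read_json(paste0(base, "_meta.json"),
                              simplifyVector = TRUE)
  structure(list(channels = ch, rate = meta$rate,
                 events = as.data.frame(meta$events),
                 attended = meta$attended),
            class = "pam_recording")
}
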