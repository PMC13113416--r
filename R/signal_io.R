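#' Write an sEMG recording to delimited text
#'
#' Signals are stored as a comma-separated file with one header row: a
#' `time_s` column followed by one column per muscle (uV), in canonical
#' muscle order. Acquisition metadata (subject, session, movement,
#' sampling rate) goes to a YAML sidecar `<path>.meta.yaml`, since the
#' signal table alone cannot carry it unambiguously.
#'
#' @param rec An `emg_recording`.
#' @param path Output file path (the sidecar is derived from it).
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  if (nrow(rec$channels) == 0L)
    stop("cannot write a recording with zero-length channels", call. = FALSE)
  n <- nrow(rec$channels)
  df <- data.frame(time_s = (seq_len(n) - 1L) / rec$sampling_rate,
                   rec$channels, check.names = FALSE)
  # 17 significant digits make the text round trip bit-exact for doubles
  fmt <- vapply(df, function(col) sprintf("%.17g", col),
                character(nrow(df)))
  fmt <- matrix(fmt, nrow = nrow(df), dimnames = list(NULL, names(df)))
  utils::write.table(fmt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  meta <- list(subject_id = rec$subject_id,
               session_id = rec$session_id,
               movement = rec$movement,
               sampling_rate = rec$sampling_rate,
               muscles = colnames(rec$channels),
               layers = unname(rec$layer_map[colnames(rec$channels)]))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Read an sEMG recording written by [write_recording()]
#'
#' Validates the header against the expected muscle set, requires every
#' signal cell to be numeric, and refuses to guess a sampling rate: it must
#' be present in the sidecar.
#'
#' @param path Path to the signal CSV.
#' @param muscles Expected channel columns, in order. Default
#'   [emg_muscles()].
#' @return An `emg_recording` equal (at full precision) to the one written.
#' @export
read_recording <- function(path, muscles = emg_muscles()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing metadata sidecar: ", sc, call. = FALSE)
  meta <- yaml::read_yaml(sc)
  if (is.null(meta$sampling_rate))
    stop("sidecar lacks sampling_rate; it is never guessed", call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  missing <- setdiff(muscles, names(df))
  if (length(missing))
    stop("signal file ", path, " is missing channel column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ch <- as.matrix(df[muscles])
  if (!is.numeric(ch)) {
    bad <- which(!apply(df[muscles], 1, function(r) all(!is.na(suppressWarnings(as.numeric(r))))))
    stop("non-numeric signal value at data row ", bad[1], call. = FALSE)
  }
  if (anyNA(ch)) {
    bad <- which(rowSums(is.na(ch)) > 0)
    stop("non-numeric signal value at data row ", bad[1], call. = FALSE)
  }
  layers <- meta$layers
  if (is.null(layers)) layers <- unname(muscle_layer_map()[muscles])
  new_emg_recording(
    subject_id = meta$subject_id,
    session_id = meta$session_id,
    movement = meta$movement,
    sampling_rate = meta$sampling_rate,
    channels = ch,
    layer_map = stats::setNames(layers, muscles)
  )
}

#' Write / read a whole cohort directory
#'
#' Layout: `dir/<subject>/<session>/<movement>.csv` plus sidecars.
#'
#' @param recordings List of `emg_recording` objects.
#' @param dir Cohort directory.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a list
#'   of recordings ordered by subject, session, movement name.
#' @export
write_cohort <- function(recordings, dir) {
  for (rec in recordings) {
    d <- file.path(dir, rec$subject_id, rec$session_id)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_recording(rec, file.path(d, paste0(rec$movement, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.csv$", recursive = TRUE,
                           full.names = TRUE))
  if (!length(paths)) stop("no recordings found under ", dir, call. = FALSE)
  lapply(paths, read_recording)
}

#' Merge one subject's sessions per movement
#'
#' For each movement, concatenates that subject's session recordings in
#' session order into one block, recording the session boundary indices so
#' that downstream RMS windows never straddle two sessions (a window across
#' the splice would mix unrelated signal and create an artificial
#' discontinuity feature).
#'
#' @param recs List of `emg_recording` objects belonging to one subject.
#' @return Named list (by movement) of merged `emg_recording` objects; each
#'   carries `session_boundaries`, the cumulative end-sample of every
#'   constituent session.
#' @export
merge_sessions <- function(recs) {
  stopifnot(length(recs) >= 1L)
  subj <- unique(vapply(recs, `[[`, "", "subject_id"))
  if (length(subj) != 1L)
    stop("merge_sessions() requires recordings from a single subject; got: ",
         paste(subj, collapse = ", "), call. = FALSE)
  fs <- unique(vapply(recs, `[[`, 0, "sampling_rate"))
  if (length(fs) != 1L)
    stop("mixed sampling rates: ", paste(fs, collapse = ", "), call. = FALSE)
  movements <- unique(vapply(recs, `[[`, "", "movement"))
  out <- lapply(movements, function(mov) {
    part <- Filter(function(r) r$movement == mov, recs)
    part <- part[order(vapply(part, `[[`, "", "session_id"))]
    ch <- do.call(rbind, lapply(part, `[[`, "channels"))
    new_emg_recording(
      subject_id = subj,
      session_id = paste(vapply(part, `[[`, "", "session_id"),
                         collapse = "+"),
      movement = mov,
      sampling_rate = fs,
      channels = ch,
      layer_map = part[[1]]$layer_map,
      session_boundaries = cumsum(vapply(part, function(r) nrow(r$channels), 0L))
    )
  })
  stats::setNames(out, movements)
}
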