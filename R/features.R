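#' Sliding-window RMS of a signal
#'
#' The k-th output value is the root mean square of samples
#' `[(k-1) * stride + 1, (k-1) * stride + window_len]`; the number of
#' windows is `floor((n - window_len) / stride) + 1`. If `boundaries`
#' (cumulative segment end indices, e.g. session splice points from
#' [merge_sessions()]) is supplied, windows are computed within each
#' segment independently so no window spans a boundary.
#'
#' @param x Numeric signal (uV).
#' @param window_len Window length in samples (default 250, i.e. 125 ms at
#'   2000 Hz).
#' @param stride Hop between window starts in samples (default
#'   `window_len`: non-overlapping).
#' @param boundaries Optional increasing integer vector of segment end
#'   indices; the last entry must be `length(x)`.
#' @return Numeric vector of RMS values (uV).
#' @examples
#' sliding_rms(rep(2, 500), window_len = 250)
#' sliding_rms(c(3, -4, 3, -4), window_len = 2, stride = 2)
#' @export
sliding_rms <- function(x, window_len = 250L, stride = window_len,
                        boundaries = NULL) {
  stopifnot(window_len >= 1L, stride >= 1L)
  if (!is.null(boundaries)) {
    stopifnot(all(diff(c(0L, boundaries)) > 0L),
              boundaries[length(boundaries)] == length(x))
    starts <- c(0L, boundaries[-length(boundaries)])
    segs <- Map(function(s, e) x[(s + 1L):e], starts, boundaries)
    return(unlist(lapply(segs, sliding_rms, window_len = window_len,
                         stride = stride), use.names = FALSE))
  }
  n <- length(x)
  if (n < window_len)
    stop("signal of length ", n, " is shorter than the ", window_len,
         "-sample window", call. = FALSE)
  n_win <- (n - window_len) %/% stride + 1L
  cs <- cumsum(c(0, x^2))
  s <- (seq_len(n_win) - 1L) * stride
  sqrt((cs[s + window_len + 1L] - cs[s + 1L]) / window_len)
}

#' Peak normalization
#'
#' Divides a group of RMS values by the group maximum so activations lie in
#' `[0, 1]` with the peak window mapping to exactly 1. In the pipeline the
#' group is one subject x muscle across both sessions and all movements;
#' this function is the per-group primitive.
#'
#' @param x Nonnegative numeric vector (one group's RMS values).
#' @return List with `values` (normalized, in `[0, 1]`) and `peak` (the
#'   group maximum, retained for the inverse transform).
#' @examples
#' peak_normalize(c(1, 2, 4))$values
#' @export
peak_normalize <- function(x) {
  if (!length(x)) stop("empty group", call. = FALSE)
  peak <- max(x)
  if (!is.finite(peak) || peak <= 0)
    stop("degenerate channel: group peak is not positive", call. = FALSE)
  list(values = x / peak, peak = peak)
}

#' Build the windowed RMS feature table for a cohort
#'
#' For every recording, computes boundary-respecting sliding-window RMS per
#' channel (all channels share the same windows), then peak-normalizes per
#' group and label-encodes the movement. The result is the feature/target
#' matrix used by the cross-subject models: one row per window with the six
#' muscles' normalized RMS, plus subject, session, movement code and window
#' index.
#'
#' @param recordings List of `emg_recording` objects (e.g. from
#'   [generate_cohort()] or [read_cohort()]).
#' @param window_len,stride Window parameters, see [sliding_rms()].
#' @param normalize Apply peak normalization (default TRUE).
#' @param peak_scope `"subject"` (default: per subject x muscle across
#'   sessions and movements, the broadest consistent scope) or
#'   `"subject_session"`.
#' @return A data.frame of class `rms_feature_table` with columns
#'   `subject_id`, `session_id`, `movement`, `movement_code`,
#'   `window_index` and one column per muscle; when normalized, the
#'   recorded peaks (uV) are attached as `attr(, "peaks")`.
#' @examples
#' cfg <- cohort_config(n_subjects = 1, n_sessions = 1,
#'                      duration_per_trial = 1, seed = 2)
#' tab <- build_feature_table(generate_cohort(cfg))
#' range(tab$medial_deltoid)
#' @export
build_feature_table <- function(recordings, window_len = 250L,
                                stride = window_len, normalize = TRUE,
                                peak_scope = c("subject", "subject_session")) {
  stopifnot(length(recordings) >= 1L)
  peak_scope <- match.arg(peak_scope)
  muscles <- colnames(recordings[[1]]$channels)
  for (rec in recordings)
    if (!identical(colnames(rec$channels), muscles))
      stop("recordings have inconsistent muscle sets", call. = FALSE)

  blocks <- lapply(recordings, function(rec) {
    rms <- vapply(muscles,
                  function(m) sliding_rms(rec$channels[, m], window_len,
                                          stride, rec$session_boundaries),
                  numeric(n_windows(rec, window_len, stride)))
    rms <- matrix(rms, ncol = length(muscles),
                  dimnames = list(NULL, muscles))
    data.frame(subject_id = rec$subject_id,
               session_id = rec$session_id,
               movement = rec$movement,
               movement_code = encode_movement(rec$movement),
               window_index = seq_len(nrow(rms)),
               rms, check.names = FALSE)
  })
  tab <- do.call(rbind, blocks)
  rownames(tab) <- NULL

  if (normalize) {
    key <- if (peak_scope == "subject") tab$subject_id
           else paste(tab$subject_id, tab$session_id)
    peaks <- list()
    for (m in muscles) {
      for (g in unique(key)) {
        idx <- key == g
        pn <- peak_normalize(tab[[m]][idx])
        tab[[m]][idx] <- pn$values
        peaks[[paste(g, m, sep = "|")]] <- pn$peak
      }
    }
    attr(tab, "peaks") <- data.frame(
      group = sub("\\|.*$", "", names(peaks)),
      muscle = sub("^.*\\|", "", names(peaks)),
      peak_uV = unlist(peaks, use.names = FALSE)
    )
  }
  attr(tab, "muscles") <- muscles
  attr(tab, "window_len") <- as.integer(window_len)
  attr(tab, "stride") <- as.integer(stride)
  class(tab) <- c("rms_feature_table", "data.frame")
  tab
}

n_windows <- function(rec, window_len, stride) {
  b <- rec$session_boundaries
  if (is.null(b)) b <- nrow(rec$channels)
  lens <- diff(c(0L, b))
  sum((lens - window_len) %/% stride + 1L)
}

#' @export
print.rms_feature_table <- function(x, ...) {
  cat(sprintf(
    "RMS feature table: %d windows, %d subject(s), %d movement(s), window %d / stride %d samples\n",
    nrow(x), length(unique(x$subject_id)), length(unique(x$movement)),
    attr(x, "window_len"), attr(x, "stride")))
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}
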