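#' Shoulder muscles and rehabilitation movements
#'
#' The package works with a fixed anatomical vocabulary: six muscles
#' instrumented with surface EMG electrodes (three superficial, three deep
#' rotator-cuff stabilizers) and four commonly prescribed shoulder
#' exercises. These constants define the canonical names and ordering used
#' throughout; channel and feature columns always follow `emg_muscles()`
#' order, and movement label codes follow `emg_movements()` order.
#'
#' @return `emg_muscles()` and `emg_movements()` return character vectors;
#'   `muscle_layer_map()` returns a named character vector mapping each
#'   muscle to `"superficial"` or `"deep"`.
#' @examples
#' emg_muscles()
#' muscle_layer_map()["supraspinatus"]
#' @export
emg_muscles <- function() {
  c("medial_deltoid", "posterior_deltoid", "trapezius",
    "supraspinatus", "infraspinatus", "teres_minor")
}

#' @rdname emg_muscles
#' @export
emg_movements <- function() {
  c("scaption", "internal_rotation_side", "external_rotation_side",
    "external_rotation_90_abduction")
}

#' @rdname emg_muscles
#' @export
muscle_layer_map <- function() {
  c(medial_deltoid    = "superficial",
    posterior_deltoid = "superficial",
    trapezius         = "superficial",
    supraspinatus     = "deep",
    infraspinatus     = "deep",
    teres_minor       = "deep")
}

#' Encode a movement name as an integer label
#'
#' Movements are label-encoded with a fixed, reproducible mapping
#' (`scaption` = 0, `internal_rotation_side` = 1, `external_rotation_side`
#' = 2, `external_rotation_90_abduction` = 3) so the encoded column can be
#' used as a model feature without run-to-run ambiguity.
#'
#' @param name Character vector of movement names.
#' @return Integer vector of codes in `0:3`.
#' @examples
#' encode_movement("scaption")
#' encode_movement(c("external_rotation_90_abduction", "scaption"))
#' @export
encode_movement <- function(name) {
  movements <- emg_movements()
  idx <- match(name, movements)
  if (anyNA(idx)) {
    bad <- unique(name[is.na(idx)])
    stop("unknown movement(s): ", paste(bad, collapse = ", "),
         "; valid movements are: ", paste(movements, collapse = ", "),
         call. = FALSE)
  }
  as.integer(idx - 1L)
}

#' Default per-muscle, per-movement amplitude gain table
#'
#' Encodes which muscles are primarily activated by each exercise:
#' scaption recruits the medial deltoid, trapezius and all three deep
#' stabilizers; external rotation at the side the posterior deltoid,
#' infraspinatus and teres minor; internal rotation at the side the medial
#' deltoid only; and external rotation at 90 degrees abduction the
#' posterior deltoid, supraspinatus and teres minor. Activated cells get
#' `high` gain, the rest `low`, so the activation pattern is recoverable by
#' downstream models but channels still overlap.
#'
#' @param high Gain (uV scale) for primarily activated muscles. Default 1.0.
#' @param low Gain for non-primary muscles. Default 0.2.
#' @return Numeric matrix, 6 muscles (rows) by 4 movements (columns).
#' @examples
#' g <- make_default_gain_table()
#' g["medial_deltoid", "scaption"]
#' @export
make_default_gain_table <- function(high = 1.0, low = 0.2) {
  stopifnot(is.numeric(high), is.numeric(low), high >= 0, low >= 0)
  muscles <- emg_muscles()
  movements <- emg_movements()
  g <- matrix(low, nrow = length(muscles), ncol = length(movements),
              dimnames = list(muscles, movements))
  activated <- list(
    scaption = c("medial_deltoid", "trapezius", "supraspinatus",
                 "infraspinatus", "teres_minor"),
    internal_rotation_side = "medial_deltoid",
    external_rotation_side = c("posterior_deltoid", "infraspinatus",
                               "teres_minor"),
    external_rotation_90_abduction = c("posterior_deltoid", "supraspinatus",
                                       "teres_minor")
  )
  for (mov in movements) g[activated[[mov]], mov] <- high
  g
}
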