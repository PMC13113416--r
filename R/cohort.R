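#' Configuration for a synthetic sEMG cohort
#'
#' Describes the acquisition conditions emulated by the generator: cohort
#' size, session count, movement and muscle sets, sampling rate, trial
#' duration, the per-(muscle, movement) amplitude gain table, the strength
#' of the latent drive shared across channels, between-subject amplitude
#' spread, additive noise floor and the pass band of all stochastic
#' content.
#'
#' Each generated channel is
#' `gain * subject_scale * envelope(t) * (rho * z(t) + sqrt(1 - rho^2) * n_m(t))
#'  + noise_floor * w_m(t)`,
#' where `z` is a band-limited latent drive shared by all six channels of a
#' recording, and `n_m`, `w_m` are independent band-limited unit-variance
#' noises. The envelope is a train of raised-cosine bursts emulating
#' repeated, controlled exercise repetitions (one repetition every
#' `envelope_period_s` seconds); `envelope_period_s = 0` gives a flat
#' envelope (sustained contraction), which removes all deterministic shared
#' amplitude structure.
#'
#' @param n_subjects Number of subjects (default 8).
#' @param n_sessions Recording sessions per subject (default 2).
#' @param movements Ordered movement names (default [emg_movements()]).
#' @param muscles Ordered muscle names (default [emg_muscles()]).
#' @param layer_map Named map muscle -> "superficial"/"deep".
#' @param sampling_rate Sampling rate in Hz (default 2000).
#' @param duration_per_trial Trial length in seconds (default 30).
#' @param gain_table 6 x 4 nonnegative gain matrix in uV
#'   (default [make_default_gain_table()]).
#' @param shared_drive_correlation rho in \[0, 1\]: weight of the latent
#'   drive shared across channels (default 0.9).
#' @param subject_scale_sd sdlog of the per-subject log-normal amplitude
#'   multiplier (default 0.2, i.e. about 20% between-subject spread).
#' @param noise_floor Additive noise amplitude in uV (default 0.05).
#' @param band Pass band `(low_hz, high_hz)` of all stochastic content,
#'   default `c(20, 450)`; must lie inside `(0, sampling_rate / 2)`.
#' @param envelope_period_s Repetition period of the raised-cosine burst
#'   envelope, seconds; 0 for a flat envelope (default 3).
#' @param seed Integer root seed; together with subject/session/movement it
#'   determines every signal bit-for-bit.
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [generate_recording()]
#' @examples
#' cfg <- cohort_config(n_subjects = 2, duration_per_trial = 2, seed = 1)
#' cfg$n_subjects
#' @export
cohort_config <- function(n_subjects = 8L,
                          n_sessions = 2L,
                          movements = emg_movements(),
                          muscles = emg_muscles(),
                          layer_map = muscle_layer_map(),
                          sampling_rate = 2000,
                          duration_per_trial = 30,
                          gain_table = make_default_gain_table(),
                          shared_drive_correlation = 0.9,
                          subject_scale_sd = 0.2,
                          noise_floor = 0.05,
                          band = c(20, 450),
                          envelope_period_s = 3,
                          seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_sessions = as.integer(n_sessions),
    movements = movements,
    muscles = muscles,
    layer_map = layer_map,
    sampling_rate = sampling_rate,
    duration_per_trial = duration_per_trial,
    gain_table = gain_table,
    shared_drive_correlation = shared_drive_correlation,
    subject_scale_sd = subject_scale_sd,
    noise_floor = noise_floor,
    band = band,
    envelope_period_s = envelope_period_s,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1L, cfg$n_sessions >= 1L,
            cfg$sampling_rate > 0, cfg$duration_per_trial > 0,
            cfg$subject_scale_sd >= 0, cfg$noise_floor >= 0,
            cfg$envelope_period_s >= 0)
  if (cfg$shared_drive_correlation < 0 || cfg$shared_drive_correlation > 1)
    stop("shared_drive_correlation must lie in [0, 1]", call. = FALSE)
  if (any(cfg$gain_table < 0))
    stop("gain_table entries must be nonnegative", call. = FALSE)
  if (!identical(sort(rownames(cfg$gain_table)), sort(cfg$muscles)))
    stop("gain_table rows must match the muscle set", call. = FALSE)
  if (!identical(sort(colnames(cfg$gain_table)), sort(cfg$movements)))
    stop("gain_table columns must match the movement set", call. = FALSE)
  if (length(cfg$band) != 2L || cfg$band[1] <= 0 || cfg$band[2] <= cfg$band[1] ||
      cfg$band[2] >= cfg$sampling_rate / 2)
    stop("band must satisfy 0 < low < high < sampling_rate / 2", call. = FALSE)
  if (!all(cfg$muscles %in% names(cfg$layer_map)))
    stop("layer_map must cover every muscle", call. = FALSE)
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic sEMG cohort configuration\n")
  cat(sprintf("  %d subject(s) x %d session(s) x %d movement(s), %g s at %g Hz\n",
              x$n_subjects, x$n_sessions, length(x$movements),
              x$duration_per_trial, x$sampling_rate))
  cat(sprintf("  band %g-%g Hz, shared-drive rho = %g, noise floor %g uV, seed %d\n",
              x$band[1], x$band[2], x$shared_drive_correlation,
              x$noise_floor, x$seed))
  invisible(x)
}

# Evaluate code under a temporary RNG seed, restoring caller state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stream seed from (root seed, subject, session, movement).
# Kept well below 2^31. Session/movement index 0 reserves per-subject streams.
derive_seed <- function(seed, subj = 0L, sess = 0L, mov = 0L) {
  base <- abs(as.integer(seed)) %% 100000L
  base * 10007L + subj * 1013L + sess * 101L + mov
}

# Unit-variance noise band-limited by a 4th-order Butterworth band-pass
# applied forward-backward; padding absorbs filter transients.
bandlimited_noise <- function(n, sampling_rate, band) {
  pad <- min(2000L, n)
  bf <- signal::butter(4, band / (sampling_rate / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2L * pad))
  x <- x[(pad + 1L):(pad + n)]
  x / stats::sd(x)
}

# Raised-cosine repetition envelope in [0, 1]; period 0 => flat envelope.
burst_envelope <- function(n, sampling_rate, period_s) {
  if (period_s <= 0) return(rep(1, n))
  t <- (seq_len(n) - 1L) / sampling_rate
  0.5 * (1 - cos(2 * pi * t / period_s))
}

#' Generate one synthetic sEMG recording
#'
#' Simulates the six-channel signal block for one subject, session and
#' movement under the model described in [cohort_config()]. The same
#' `(seed, subject, session, movement)` always reproduces the identical
#' signal bit-for-bit, and the per-subject amplitude multiplier is drawn
#' from a stream that depends only on `(seed, subject)` so it is shared
#' across that subject's sessions and movements.
#'
#' @param config A [cohort_config()].
#' @param subject_id Subject index (1-based) or id of the form `"S3"`.
#' @param session_id Session index (1-based) or id of the form `"sess2"`.
#' @param movement A movement name from `config$movements`.
#' @return An `emg_recording`: list with `subject_id`, `session_id`,
#'   `movement`, `sampling_rate`, `channels` (numeric matrix, samples x 6
#'   muscles, uV) and `layer_map`.
#' @examples
#' cfg <- cohort_config(n_subjects = 1, duration_per_trial = 1, seed = 7)
#' rec <- generate_recording(cfg, 1, 1, "scaption")
#' dim(rec$channels)
#' @export
generate_recording <- function(config, subject_id, session_id, movement) {
  validate_cohort_config(config)
  if (!movement %in% config$movements)
    stop("unknown movement '", movement, "'; valid movements are: ",
         paste(config$movements, collapse = ", "), call. = FALSE)
  subj <- parse_index(subject_id, "S")
  sess <- parse_index(session_id, "sess")
  mov <- match(movement, config$movements)

  n <- round(config$duration_per_trial * config$sampling_rate)
  rho <- config$shared_drive_correlation
  scale_subj <- with_seed(derive_seed(config$seed, subj),
                          stats::rlnorm(1, 0, config$subject_scale_sd))
  env <- burst_envelope(n, config$sampling_rate, config$envelope_period_s)

  channels <- with_seed(derive_seed(config$seed, subj, sess, mov), {
    z <- bandlimited_noise(n, config$sampling_rate, config$band)
    out <- matrix(0, nrow = n, ncol = length(config$muscles),
                  dimnames = list(NULL, config$muscles))
    for (m in config$muscles) {
      nm <- bandlimited_noise(n, config$sampling_rate, config$band)
      wm <- bandlimited_noise(n, config$sampling_rate, config$band)
      drive <- rho * z + sqrt(1 - rho^2) * nm
      out[, m] <- config$gain_table[m, movement] * scale_subj * env * drive +
        config$noise_floor * wm
    }
    out
  })

  new_emg_recording(
    subject_id = paste0("S", subj),
    session_id = paste0("sess", sess),
    movement = movement,
    sampling_rate = config$sampling_rate,
    channels = channels,
    layer_map = config$layer_map
  )
}

parse_index <- function(id, prefix) {
  if (is.numeric(id)) return(as.integer(id))
  as.integer(sub(paste0("^", prefix), "", as.character(id)))
}

new_emg_recording <- function(subject_id, session_id, movement,
                              sampling_rate, channels, layer_map,
                              session_boundaries = NULL) {
  stopifnot(is.matrix(channels), nrow(channels) > 0, sampling_rate > 0)
  if (ncol(channels) != length(layer_map))
    stop("recording must carry one channel per mapped muscle", call. = FALSE)
  structure(list(
    subject_id = subject_id,
    session_id = session_id,
    movement = movement,
    sampling_rate = sampling_rate,
    channels = channels,
    layer_map = layer_map,
    session_boundaries = session_boundaries
  ), class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("sEMG recording: %s / %s / %s\n", x$subject_id, x$session_id,
              x$movement))
  cat(sprintf("  %d samples x %d channels at %g Hz (%.2f s)\n",
              nrow(x$channels), ncol(x$channels), x$sampling_rate,
              nrow(x$channels) / x$sampling_rate))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Produces one [generate_recording()] per subject x session x movement;
#' with the defaults (8 subjects, 2 sessions, 4 movements) that is 64
#' recordings. Regeneration with an identical config is bit-identical.
#'
#' @param config A [cohort_config()].
#' @return List of `emg_recording` objects, ordered by subject, then
#'   session, then movement.
#' @examples
#' cfg <- cohort_config(n_subjects = 1, n_sessions = 1,
#'                      duration_per_trial = 0.5, seed = 3)
#' length(generate_cohort(cfg))
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  recs <- vector("list", config$n_subjects * config$n_sessions *
                   length(config$movements))
  k <- 0L
  for (subj in seq_len(config$n_subjects)) {
    for (sess in seq_len(config$n_sessions)) {
      for (mov in config$movements) {
        k <- k + 1L
        recs[[k]] <- generate_recording(config, subj, sess, mov)
      }
    }
  }
  recs
}
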