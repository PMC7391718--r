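#' Configuration for a synthetic two-session EEG population
#'
#' Bundles all parameters of the synthetic-data generator: a population of
#' subjects, each with a latent pairwise phase-coupling matrix, recorded in two
#' sessions as multichannel oscillatory signals plus noise. Defaults emulate a
#' data-limited developmental recording: 32 channels, a 7 Hz alpha-range
#' oscillation (infant alpha, 6-8 Hz), variable-length clean segments summing
#' to three minutes per session, and substantial broadband sensor noise.
#'
#' The coupling model is
#' \deqn{c_{ij}^{(s)} = \mathrm{clip}_{[0,1]}(\mu + T_{ij} + g_s),}
#' where \eqn{\mu} = `coupling_mean`, \eqn{T_{ij}} is a population-level
#' topology pattern (SD `coupling_sd_pairs`, shared by all subjects) and
#' \eqn{g_s \sim N(0, \texttt{coupling\_sd\_between}^2)} is the subject's trait
#' offset. Each session perturbs the subject matrix by a session-level offset
#' with SD `session_noise_sd`. Ignoring clipping, the designed test-retest
#' reliability ceiling for any affine function of mean coupling is
#' \deqn{\rho = \sigma_b^2 / (\sigma_b^2 + \sigma_w^2)}
#' with \eqn{\sigma_b} = `coupling_sd_between`, \eqn{\sigma_w} =
#' `session_noise_sd` (see [design_session_noise()]).
#'
#' @param n_subjects Number of subjects.
#' @param n_channels Number of channels (electrodes); at least 2.
#' @param sampling_rate Sampling rate in Hz; must exceed twice
#'   `oscillation_freq`.
#' @param oscillation_freq Frequency (Hz) of the band-limited oscillation
#'   carrying the phase coupling. Default 7 Hz, centre of the 6-8 Hz band.
#' @param coupling_mean Population mean pairwise coupling strength in `[0, 1]`.
#' @param coupling_sd_between Between-subject SD of the trait coupling offset.
#' @param coupling_sd_pairs SD of the fixed population topology pattern over
#'   channel pairs.
#' @param session_noise_sd Within-subject, between-session SD of the coupling
#'   offset (day-to-day state variation).
#' @param sensor_noise_sd SD of white additive sensor noise per sample, in
#'   units of the unit oscillation amplitude.
#' @param mixing_strength Zero-lag (instantaneous) leakage in `[0, 1)`:
#'   fraction of each channel replaced by the average of the others,
#'   emulating volume conduction.
#' @param segment_lengths Durations (s) of the clean data segments available
#'   per session. The default mixture of 12-30 s blocks totals 180 s so every
#'   segmentation scheme up to 150 x 1 s and 20 x 6 s is satisfiable.
#' @param coherence_time Time scale (s) over which channel phase jitter
#'   decorrelates: jitter is constant within windows of this length and
#'   redrawn independently at window boundaries (which coincide with the
#'   epoch grid for integer epoch lengths).
#' @param pink_noise If `TRUE`, sensor noise is 1/f-shaped instead of white.
#'   Band-limited analysis at 6-8 Hz makes the spectral slope secondary, so
#'   white noise is the default.
#' @param seed Integer seed; together with the config it fully determines the
#'   population and recordings.
#' @return An object of class `"population_config"` (a named list).
#' @seealso [make_population()], [simulate_session()], [simulate_study()]
#' @examples
#' cfg <- population_config(n_subjects = 4, n_channels = 8, seed = 1)
#' cfg$oscillation_freq
#' @export
population_config <- function(n_subjects,
                              n_channels = 32,
                              sampling_rate = 512,
                              oscillation_freq = 7,
                              coupling_mean = 0.5,
                              coupling_sd_between = 0.1,
                              coupling_sd_pairs = 0.08,
                              session_noise_sd = 0.065,
                              sensor_noise_sd = 2,
                              mixing_strength = 0,
                              segment_lengths = c(30, 24, 18, 30, 12, 24, 18, 24),
                              coherence_time = 1,
                              pink_noise = FALSE,
                              seed = 1L) {
  check_scalar_number(n_subjects, "n_subjects", min = 1)
  check_scalar_number(n_channels, "n_channels", min = 2)
  check_scalar_number(sampling_rate, "sampling_rate", min = 0, strict_min = TRUE)
  check_scalar_number(oscillation_freq, "oscillation_freq", min = 0, strict_min = TRUE)
  if (sampling_rate <= 2 * oscillation_freq)
    stop_config("sampling_rate (%g Hz) must exceed twice oscillation_freq (%g Hz)",
                sampling_rate, oscillation_freq)
  check_scalar_number(coupling_mean, "coupling_mean", min = 0, max = 1)
  check_scalar_number(coupling_sd_between, "coupling_sd_between", min = 0)
  check_scalar_number(coupling_sd_pairs, "coupling_sd_pairs", min = 0)
  check_scalar_number(session_noise_sd, "session_noise_sd", min = 0)
  check_scalar_number(sensor_noise_sd, "sensor_noise_sd", min = 0)
  check_scalar_number(mixing_strength, "mixing_strength", min = 0, max = 1,
                      strict_max = TRUE)
  check_scalar_number(coherence_time, "coherence_time", min = 0, strict_min = TRUE)
  if (!is.numeric(segment_lengths) || length(segment_lengths) < 1 ||
      any(segment_lengths < 1))
    stop_config("segment_lengths must be durations of at least 1 s")
  check_scalar_number(seed, "seed")

  structure(list(
    n_subjects = as.integer(n_subjects),
    n_channels = as.integer(n_channels),
    sampling_rate = sampling_rate,
    oscillation_freq = oscillation_freq,
    coupling_mean = coupling_mean,
    coupling_sd_between = coupling_sd_between,
    coupling_sd_pairs = coupling_sd_pairs,
    session_noise_sd = session_noise_sd,
    sensor_noise_sd = sensor_noise_sd,
    mixing_strength = mixing_strength,
    segment_lengths = as.numeric(segment_lengths),
    coherence_time = coherence_time,
    pink_noise = pink_noise,
    seed = as.integer(seed)
  ), class = "population_config")
}

#' @export
print.population_config <- function(x, ...) {
  cat("<population_config>\n")
  cat(sprintf("  %d subjects x %d channels @ %g Hz, oscillation %g Hz\n",
              x$n_subjects, x$n_channels, x$sampling_rate, x$oscillation_freq))
  cat(sprintf("  coupling %.2f (between-subject sd %.3f, topology sd %.3f)\n",
              x$coupling_mean, x$coupling_sd_between, x$coupling_sd_pairs))
  cat(sprintf("  session noise sd %.3f, sensor noise sd %.2f, mixing %.2f\n",
              x$session_noise_sd, x$sensor_noise_sd, x$mixing_strength))
  cat(sprintf("  segments: %s s (total %g s), seed %d\n",
              paste(x$segment_lengths, collapse = ", "),
              sum(x$segment_lengths), x$seed))
  invisible(x)
}

#' Session-noise SD achieving a designed reliability ratio
#'
#' Inverts \eqn{\rho = \sigma_b^2 / (\sigma_b^2 + \sigma_w^2)} to give the
#' between-session coupling SD that makes the designed variance ratio of the
#' generator equal `rho`, for a given between-subject SD.
#'
#' @param rho Target variance ratio (designed ICC ceiling) in `(0, 1]`.
#' @param coupling_sd_between Between-subject coupling SD.
#' @return The `session_noise_sd` to pass to [population_config()].
#' @examples
#' design_session_noise(0.7, 0.1)
#' @export
design_session_noise <- function(rho, coupling_sd_between) {
  check_scalar_number(rho, "rho", min = 0, max = 1, strict_min = TRUE)
  check_scalar_number(coupling_sd_between, "coupling_sd_between", min = 0)
  coupling_sd_between * sqrt((1 - rho) / rho)
}

#' Draw a population of subject coupling models
#'
#' Each subject receives a symmetric `true_coupling` matrix in `[0, 1]` (zero
#' diagonal) and an antisymmetric `pair_lags` matrix of mean phase offsets
#' (radians). Coupling is the population mean plus a shared topology pattern
#' plus a subject trait offset, clipped to `[0, 1]`; with
#' `coupling_sd_between = 0` all subjects share an identical matrix.
#'
#' Because signals are generated per channel from a common oscillator, mean
#' pair lags are necessarily differences of per-channel offsets. Offsets are
#' drawn in two phase clusters (0 and pi/2, each jittered by +/- pi/8), so
#' roughly half of all pairs have lags near pi/2 — where lagged-coupling
#' estimators are most informative — while within-cluster pairs have small,
#' volume-conduction-like lags.
#'
#' @param config A [population_config()].
#' @return A list of `"subject_model"` objects with fields `subject_id`,
#'   `true_coupling`, `pair_lags`, `channel_offsets`.
#' @examples
#' pop <- make_population(population_config(n_subjects = 3, n_channels = 8))
#' pop[[1]]$true_coupling[1:3, 1:3]
#' @export
make_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  nc <- config$n_channels
  with_seed(substream_seed(config$seed, "population"), {
    topology <- matrix(0, nc, nc)
    iu <- upper_pairs(nc)
    topology[iu] <- stats::rnorm(length(iu), 0, config$coupling_sd_pairs)
    topology <- topology + t(topology)
    lapply(seq_len(config$n_subjects), function(s) {
      g <- stats::rnorm(1, 0, config$coupling_sd_between)
      coupling <- clip01(config$coupling_mean + topology + g)
      diag(coupling) <- 0
      # two phase clusters at 0 and pi/2, jittered; lags = outer difference
      cluster <- rep(c(0, pi / 2), length.out = nc)
      offsets <- cluster + stats::runif(nc, -pi / 8, pi / 8)
      lags <- outer(offsets, offsets, "-")
      new_subject_model(sprintf("S%03d", s), coupling, lags, offsets)
    })
  })
}

new_subject_model <- function(subject_id, true_coupling, pair_lags,
                              channel_offsets = NULL) {
  check_square_symmetric(true_coupling, "true_coupling")
  if (any(true_coupling < 0 | true_coupling > 1))
    stop_config("true_coupling must lie in [0, 1]")
  if (max(abs(pair_lags + t(pair_lags))) > 1e-10)
    stop_config("pair_lags must be antisymmetric")
  structure(list(subject_id = subject_id,
                 true_coupling = true_coupling,
                 pair_lags = pair_lags,
                 channel_offsets = channel_offsets),
            class = "subject_model")
}

#' Construct a subject model directly
#'
#' Escape hatch for controlled experiments and tests: supply the coupling
#' matrix and either per-channel phase offsets (from which `pair_lags` is the
#' outer difference) or a full antisymmetric lag matrix.
#'
#' @param true_coupling Symmetric coupling matrix in `[0, 1]`, zero diagonal.
#' @param channel_offsets Optional numeric vector of per-channel phase
#'   offsets (radians).
#' @param pair_lags Optional antisymmetric lag matrix; defaults to the outer
#'   difference of `channel_offsets`.
#' @param subject_id Identifier string.
#' @return A `"subject_model"`.
#' @examples
#' m <- subject_model(matrix(c(0, 1, 1, 0), 2), channel_offsets = c(pi / 2, 0))
#' m$pair_lags
#' @export
subject_model <- function(true_coupling, channel_offsets = NULL,
                          pair_lags = NULL, subject_id = "S001") {
  if (is.null(pair_lags)) {
    if (is.null(channel_offsets))
      stop_config("supply channel_offsets or pair_lags")
    pair_lags <- outer(channel_offsets, channel_offsets, "-")
  }
  diag(true_coupling) <- 0
  new_subject_model(subject_id, true_coupling, pair_lags, channel_offsets)
}
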