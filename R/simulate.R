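# Signal generator: common 7 Hz oscillator, per-channel phase jitter whose
# cross-channel covariance is solved from the target pair couplings, optional
# instantaneous mixing, additive sensor noise.

# Coupling strength c maps to phase-difference jitter variance v = -2 log c,
# so the resultant length (phase-locking) of the pair difference is c itself.
# Couplings below C_FLOOR are treated as fully unlocked.
C_FLOOR <- 0.02

coupling_to_variance <- function(coupling) {
  -2 * log(pmax(coupling, C_FLOOR))
}

# Solve a channel-jitter covariance Sigma such that
# Var(eps_i - eps_j) = Sigma_ii + Sigma_jj - 2 Sigma_ij = v_ij for all pairs,
# then return a factor L with Sigma ~= L L'. The target system is solved with
# Sigma_ii = rowmean(v)/2 and symmetrised; negative eigenvalues (possible for
# strongly heterogeneous targets) are clipped to zero, which slightly smooths
# extreme coupling contrasts.
jitter_factor <- function(v) {
  nc <- nrow(v)
  diag(v) <- 0
  a <- rowSums(v) / (2 * (nc - 1))
  if (nc == 2) a <- rep(v[1, 2] / 2, 2)
  sigma <- (outer(a, a, "+") - v) / 2
  diag(sigma) <- a
  if (all(abs(sigma) < 1e-14)) return(matrix(0, nc, nc))
  e <- eigen(sigma, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# 1/f-shaped noise matrix (ns x nc), unit marginal SD
pink_noise_matrix <- function(ns, nc) {
  freqs <- c(1, seq_len(ns - 1))
  scale <- 1 / sqrt(pmin(freqs, ns - freqs + 1))
  x <- vapply(seq_len(nc), function(j) {
    spec <- stats::fft(stats::rnorm(ns)) * scale
    Re(stats::fft(spec, inverse = TRUE)) / ns
  }, numeric(ns))
  x <- as.matrix(x)
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

#' Simulate one session's continuous recording for a subject
#'
#' Generates the clean data segments of one session: every channel carries a
#' common oscillation at the configured frequency, shifted by the channel's
#' phase offset and by slowly varying phase jitter whose cross-channel
#' covariance realises the subject's (session-perturbed) pair couplings.
#' Optional instantaneous mixing replaces a fraction `mixing_strength` of each
#' channel with the mean of the others (zero-lag leakage), and white (or 1/f)
#' sensor noise is added per sample.
#'
#' @param model A `"subject_model"`.
#' @param config The [population_config()].
#' @param session_id Session number, 1 or 2.
#' @param seed Optional integer seed; defaults to a substream of
#'   `config$seed` keyed by subject and session.
#' @return A `"continuous_recording"`: list with `subject_id`, `session_id`,
#'   `segments` (list of channels x samples matrices), `sampling_rate`.
#' @examples
#' cfg <- population_config(n_subjects = 1, n_channels = 4, sampling_rate = 128,
#'                          segment_lengths = c(4, 6))
#' rec <- simulate_session(make_population(cfg)[[1]], cfg, 1)
#' vapply(rec$segments, ncol, integer(1))
#' @export
simulate_session <- function(model, config, session_id, seed = NULL) {
  stopifnot(inherits(model, "subject_model"),
            inherits(config, "population_config"))
  if (!session_id %in% c(1, 2))
    stop_config("session_id must be 1 or 2")
  if (is.null(seed))
    seed <- substream_seed(config$seed, "session", model$subject_id, session_id)
  nc <- nrow(model$true_coupling)
  fs <- config$sampling_rate
  offsets <- model$channel_offsets
  if (is.null(offsets)) offsets <- rep(0, nc)

  with_seed(seed, {
    shift <- stats::rnorm(1, 0, config$session_noise_sd)
    coupling <- clip01(model$true_coupling + shift)
    diag(coupling) <- 0
    L <- jitter_factor(coupling_to_variance(coupling))

    segments <- lapply(config$segment_lengths, function(len) {
      ns <- round(len * fs)
      tt <- (seq_len(ns) - 1) / fs
      theta0 <- stats::runif(1, 0, 2 * pi)
      base <- 2 * pi * config$oscillation_freq * tt + theta0

      # jitter is constant within coherence windows and redrawn independently
      # at window boundaries; windows align with the epoch grid, so 1-s
      # epochs see a single phase state and the resultant length of the pair
      # phase difference equals the coupling strength exactly
      knots <- seq(0, by = config$coherence_time,
                   length.out = ceiling(len / config$coherence_time) + 1)
      z <- matrix(stats::rnorm(length(knots) * nc), length(knots), nc)
      eknots <- z %*% t(L)
      eps <- vapply(seq_len(nc), function(ch) {
        stats::approx(knots, eknots[, ch], xout = tt, method = "constant",
                      rule = 2)$y
      }, numeric(ns))

      x <- cos(base + rep(offsets, each = ns) + eps)  # ns x nc
      m <- config$mixing_strength
      if (m > 0) {
        mix <- (1 - m) * diag(nc) + (m / (nc - 1)) * (1 - diag(nc))
        x <- x %*% mix
      }
      if (config$sensor_noise_sd > 0) {
        noise <- if (config$pink_noise) pink_noise_matrix(ns, nc)
                 else matrix(stats::rnorm(ns * nc), ns, nc)
        x <- x + config$sensor_noise_sd * noise
      }
      t(x)
    })
    new_continuous_recording(model$subject_id, session_id, segments, fs)
  })
}

new_continuous_recording <- function(subject_id, session_id, segments,
                                     sampling_rate) {
  nch <- unique(vapply(segments, nrow, integer(1)))
  if (length(nch) != 1)
    stop_config("all segments must have the same number of channels")
  structure(list(subject_id = subject_id, session_id = session_id,
                 segments = segments, sampling_rate = sampling_rate,
                 n_channels = nch),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  durs <- vapply(x$segments, ncol, integer(1)) / x$sampling_rate
  cat(sprintf("<continuous_recording> %s session %d: %d channels @ %g Hz\n",
              x$subject_id, x$session_id, x$n_channels, x$sampling_rate))
  cat(sprintf("  %d segments (%s s), total %g s\n", length(durs),
              paste(signif(durs, 3), collapse = ", "), sum(durs)))
  invisible(x)
}

#' Simulate a full two-session study
#'
#' Draws the population and both sessions for every subject.
#'
#' @param config A [population_config()].
#' @param population Optional pre-drawn population (list of subject models);
#'   drawn from `config` if omitted.
#' @return A tibble with columns `subject_id`, `session_id`, `recording`
#'   (list-column of `"continuous_recording"`), and `model` (list-column).
#' @examples
#' cfg <- population_config(n_subjects = 2, n_channels = 4, sampling_rate = 64,
#'                          segment_lengths = c(4, 4))
#' simulate_study(cfg)
#' @export
simulate_study <- function(config, population = NULL) {
  stopifnot(inherits(config, "population_config"))
  if (is.null(population)) population <- make_population(config)
  grid <- tidyr::expand_grid(subject = seq_along(population), session_id = 1:2)
  tibble::tibble(
    subject_id = vapply(population[grid$subject], `[[`, "", "subject_id"),
    session_id = grid$session_id,
    model = population[grid$subject],
    recording = purrr::map2(population[grid$subject], grid$session_id,
                            function(m, s) simulate_session(m, config, s))
  )
}
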