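noiseless_cfg <- function(n_channels, segment_lengths = 10, fs = 64) {
  population_config(n_subjects = 1, n_channels = n_channels,
                    sampling_rate = fs, sensor_noise_sd = 0,
                    session_noise_sd = 0, segment_lengths = segment_lengths,
                    seed = 3)
}

test_that("recordings are deterministic given seed and differ across sessions", {
  cfg <- tiny_config()
  m <- make_population(cfg)[[1]]
  r1 <- simulate_session(m, cfg, 1)
  r2 <- simulate_session(m, cfg, 1)
  expect_identical(r1, r2)
  r_other <- simulate_session(m, cfg, 2)
  expect_false(identical(r1$segments[[1]], r_other$segments[[1]]))
})

test_that("segments have the configured shape", {
  cfg <- tiny_config()
  rec <- simulate_session(make_population(cfg)[[1]], cfg, 1)
  expect_length(rec$segments, length(cfg$segment_lengths))
  expect_equal(vapply(rec$segments, nrow, integer(1)),
               rep(cfg$n_channels, length(cfg$segment_lengths)))
  expect_equal(vapply(rec$segments, ncol, integer(1)),
               as.integer(cfg$segment_lengths * cfg$sampling_rate))
  expect_error(simulate_session(make_population(cfg)[[1]], cfg, 3),
               "session_id")
})

test_that("noiseless perfect coupling fixes the phase difference at the lag", {
  m <- subject_model(matrix(c(0, 1, 1, 0), 2), channel_offsets = c(pi / 2, 0))
  rec <- simulate_session(m, noiseless_cfg(2), 1)
  sc <- fourier_coefficients(cut_epochs(rec, 1))
  bin7 <- which(sc$bin_frequencies == 7)
  dphi <- Arg(sc$coefficients[, 1, bin7] * Conj(sc$coefficients[, 2, bin7]))
  expect_equal(dphi, rep(pi / 2, length(dphi)), tolerance = 1e-6)
})

test_that("circular mean phase differences reproduce the constructed lags", {
  offsets <- c(0.2, 0.9, 1.5, 0.4)
  coupling <- matrix(1, 4, 4) - diag(4)
  m <- subject_model(coupling, channel_offsets = offsets)
  rec <- simulate_session(m, noiseless_cfg(4, segment_lengths = 20), 1)
  sc <- fourier_coefficients(cut_epochs(rec, 1))
  bin7 <- which(sc$bin_frequencies == 7)
  z <- sc$coefficients[, , bin7]
  for (i in 1:3) {
    for (j in (i + 1):4) {
      circ_mean <- Arg(mean(exp(1i * Arg(z[, i] * Conj(z[, j])))))
      expect_equal(circ_mean, m$pair_lags[i, j], tolerance = 1e-6)
    }
  }
})

test_that("uncoupled unmixed channels show near-zero dbWPLI", {
  cfg <- population_config(n_subjects = 1, n_channels = 6, sampling_rate = 64,
                           coupling_mean = 0, coupling_sd_between = 0,
                           coupling_sd_pairs = 0, segment_lengths = c(60, 60),
                           seed = 17)
  rec <- simulate_session(make_population(cfg)[[1]], cfg, 1)
  d <- dbwpli_matrix(fourier_coefficients(cut_epochs(rec, 1)))
  expect_lt(abs(whole_brain(d)), 0.03)
})

test_that("session noise perturbs coupling between sessions", {
  cfg <- population_config(n_subjects = 1, n_channels = 8, sampling_rate = 64,
                           session_noise_sd = 0.3, sensor_noise_sd = 0,
                           segment_lengths = 30, seed = 21)
  m <- make_population(cfg)[[1]]
  wb <- vapply(1:2, function(s) {
    whole_brain(dbwpli_matrix(fourier_coefficients(
      cut_epochs(simulate_session(m, cfg, s), 1))))
  }, numeric(1))
  expect_false(isTRUE(all.equal(wb[1], wb[2], tolerance = 1e-6)))
})

test_that("pink sensor noise is accepted and produces finite signal", {
  cfg <- population_config(n_subjects = 1, n_channels = 4, sampling_rate = 64,
                           pink_noise = TRUE, segment_lengths = 5, seed = 2)
  rec <- simulate_session(make_population(cfg)[[1]], cfg, 1)
  expect_true(all(is.finite(rec$segments[[1]])))
})

test_that("simulate_study returns one recording per subject and session", {
  cfg <- tiny_config()
  study <- simulate_study(cfg)
  expect_equal(nrow(study), 2 * cfg$n_subjects)
  expect_s3_class(study$recording[[1]], "continuous_recording")
  expect_setequal(study$session_id, 1:2)
})
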