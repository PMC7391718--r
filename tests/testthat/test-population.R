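test_that("config validation rejects impossible parameters", {
  expect_error(population_config(n_subjects = 5, coupling_sd_between = -0.1),
               "coupling_sd_between")
  expect_error(population_config(n_subjects = 5, sampling_rate = 12,
                                 oscillation_freq = 7), "Nyquist|exceed")
  expect_error(population_config(n_subjects = 5, n_channels = 1),
               "n_channels")
  expect_error(population_config(n_subjects = 5, mixing_strength = 1),
               "mixing_strength")
  expect_error(population_config(n_subjects = 5, segment_lengths = 0.5),
               "segment_lengths")
})

test_that("populations are reproducible from the seed", {
  cfg <- population_config(n_subjects = 5, n_channels = 8, seed = 42)
  p1 <- make_population(cfg)
  p2 <- make_population(cfg)
  expect_identical(p1, p2)
  p3 <- make_population(population_config(n_subjects = 5, n_channels = 8,
                                          seed = 43))
  expect_false(identical(p1[[1]]$true_coupling, p3[[1]]$true_coupling))
})

test_that("zero between-subject variance gives identical coupling matrices", {
  cfg <- population_config(n_subjects = 4, n_channels = 8,
                           coupling_sd_between = 0, seed = 5)
  pop <- make_population(cfg)
  for (s in 2:4)
    expect_identical(pop[[s]]$true_coupling, pop[[1]]$true_coupling)
})

test_that("subject models satisfy their structural invariants", {
  cfg <- population_config(n_subjects = 6, n_channels = 12, seed = 9)
  for (m in make_population(cfg)) {
    expect_equal(m$true_coupling, t(m$true_coupling))
    expect_true(all(diag(m$true_coupling) == 0))
    expect_true(all(m$true_coupling >= 0 & m$true_coupling <= 1))
    expect_equal(m$pair_lags, -t(m$pair_lags), tolerance = 1e-12)
  }
})

test_that("between-subject spread of mean coupling matches the closed form", {
  # subject trait offsets are shared across pairs, so SD(per-subject mean
  # coupling) = coupling_sd_between exactly (up to clipping, negligible here)
  cfg <- population_config(n_subjects = 40, n_channels = 32,
                           coupling_mean = 0.5, coupling_sd_between = 0.1,
                           seed = 20)
  pop <- make_population(cfg)
  means <- vapply(pop, function(m) {
    w <- m$true_coupling
    mean(w[upper.tri(w)])
  }, numeric(1))
  expect_lt(abs(stats::sd(means) - 0.1) / 0.1, 0.3)
})

test_that("design_session_noise inverts the variance-ratio formula", {
  sw <- design_session_noise(0.7, 0.1)
  expect_equal(0.1^2 / (0.1^2 + sw^2), 0.7, tolerance = 1e-12)
})

test_that("seed substreams are deterministic and well separated", {
  expect_identical(substream_seed(1, "subject", 3), substream_seed(1, "subject", 3))
  keys <- expand.grid(a = 1:20, b = 1:20)
  seeds <- mapply(function(a, b) substream_seed(5, a, b), keys$a, keys$b)
  expect_equal(anyDuplicated(seeds), 0L)
  expect_false(substream_seed(1, "x") == substream_seed(2, "x"))
})

test_that("subject_model accepts explicit lags and validates them", {
  w <- matrix(c(0, 0.5, 0.5, 0), 2)
  m <- subject_model(w, channel_offsets = c(pi / 2, 0))
  expect_equal(m$pair_lags[1, 2], pi / 2)
  bad_lags <- matrix(c(0, 1, 1, 0), 2)  # not antisymmetric
  expect_error(subject_model(w, pair_lags = bad_lags), "antisymmetric")
})
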