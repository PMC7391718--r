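test_that("spectral resolution follows 1/epoch_length", {
  cfg <- population_config(n_subjects = 1, n_channels = 2,
                           sampling_rate = 512, segment_lengths = 4, seed = 1)
  rec <- simulate_session(make_population(cfg)[[1]], cfg, 1)
  sc1 <- fourier_coefficients(cut_epochs(rec, 1))
  expect_equal(diff(sc1$bin_frequencies)[1], 1)
  expect_equal(sum(sc1$bin_frequencies >= 6 & sc1$bin_frequencies <= 8), 3)
  sc2 <- fourier_coefficients(cut_epochs(rec, 2))
  expect_equal(diff(sc2$bin_frequencies)[1], 0.5)
  expect_equal(sum(sc2$bin_frequencies >= 6 & sc2$bin_frequencies <= 8), 5)
})

test_that("a pure sinusoid concentrates at its bin with the signal phase", {
  fs <- 64
  tt <- (0:(fs - 1)) / fs
  phase <- 0.8
  x <- rbind(cos(2 * pi * 7 * tt + phase), cos(2 * pi * 7 * tt))
  es <- eegicc:::new_epoch_set("T", 1, 1, list(x), fs)
  sc <- fourier_coefficients(es)
  mags <- abs(sc$coefficients[1, 1, ])
  expect_equal(which.max(mags), which(sc$bin_frequencies == 7))
  # Hann mainlobe spans the two adjacent bins at half amplitude;
  # everything else is numerically zero for an on-bin sinusoid
  expect_gt(mags[8], 1.9 * max(mags[c(7, 9)]))
  expect_lt(max(mags[-(7:9)]), 1e-8 * mags[8])
  expect_equal(Arg(sc$coefficients[1, 1, 8]), phase, tolerance = 1e-6)
  expect_error(fourier_coefficients(eegicc:::new_epoch_set("T", 1, 1,
                                                           list(), fs)),
               "empty")
})

test_that("PLI reproduces hand-computed sign averages", {
  # imaginary cross-spectrum signs (+, +, -, +) -> |(1 + 1 - 1 + 1) / 4|
  signs <- c(1, 1, -1, 1)
  z <- array(complex(real = 1), dim = c(4, 2, 1))
  z[, 2, 1] <- exp(-1i * signs * pi / 2)
  sc <- make_coeffs(z, bin_frequencies = 7)
  expect_equal(pli_matrix(sc, c(6, 8))$weights[1, 2], 0.5)
})

test_that("constant non-zero lag with equal magnitudes gives exactly 1", {
  theta <- runif(12, 0, 2 * pi)
  z <- array(0i, dim = c(12, 2, 1))
  z[, 1, 1] <- exp(1i * theta)
  z[, 2, 1] <- exp(1i * (theta - pi / 2))
  sc <- make_coeffs(z, bin_frequencies = 7)
  expect_equal(pli_matrix(sc)$weights[1, 2], 1, tolerance = 1e-12)
  expect_equal(dbwpli_matrix(sc)$weights[1, 2], 1, tolerance = 1e-12)
  expect_equal(wpli_matrix(sc)$weights[1, 2], 1, tolerance = 1e-12)
})

test_that("a purely real cross-spectrum (zero-lag) yields zero", {
  # coefficients with a common (zero) phase: the cross-spectrum is real and
  # its imaginary part is exactly zero, so sgn(0) = 0 applies
  z <- array(0i, dim = c(10, 2, 1))
  z[, 1, 1] <- complex(real = runif(10, 0.5, 2))
  z[, 2, 1] <- complex(real = c(-1, 1)[rep_len(1:2, 10)] * runif(10, 0.5, 2))
  sc <- make_coeffs(z, bin_frequencies = 7)
  expect_equal(dbwpli_matrix(sc)$weights[1, 2], 0)
  expect_equal(pli_matrix(sc)$weights[1, 2], 0)
  expect_equal(wpli_matrix(sc)$weights[1, 2], 0)
})

test_that("connectivity matrices are exactly symmetric and bounded", {
  withr_seed <- 99; set.seed(withr_seed)
  sc <- gaussian_coeffs(25, 6)
  for (f in list(pli_matrix, dbwpli_matrix, wpli_matrix)) {
    w <- f(sc)$weights
    expect_identical(w, t(w))
    expect_true(all(diag(w) == 0))
    expect_true(all(w >= -1 & w <= 1))
  }
  expect_true(all(pli_matrix(sc)$weights >= 0))
  expect_true(all(wpli_matrix(sc)$weights >= 0))
})

test_that("band averaging of identical per-bin matrices is the identity", {
  set.seed(5)
  z1 <- gaussian_coeffs(20, 4)$coefficients
  z <- array(0i, dim = c(20, 4, 3))
  for (b in 1:3) z[, , b] <- z1[, , 1]
  sc <- make_coeffs(z, bin_frequencies = 6:8)
  sc1 <- make_coeffs(z1, bin_frequencies = 7)
  expect_equal(pli_matrix(sc, c(6, 8))$weights, pli_matrix(sc1)$weights)
  expect_equal(dbwpli_matrix(sc, c(6, 8))$weights, dbwpli_matrix(sc1)$weights)
})

test_that("band and epoch-count preconditions are enforced", {
  set.seed(6)
  sc <- gaussian_coeffs(10, 3)
  expect_error(pli_matrix(sc, c(20, 30)), "no frequency bins")
  one <- make_coeffs(sc$coefficients[1, , , drop = FALSE], 7)
  expect_error(dbwpli_matrix(one), "at least 2 epochs")
  expect_equal(dim(pli_matrix(one)$weights), c(3, 3))  # PLI works at n = 1
})

test_that("whole-brain connectivity is the mean over distinct pairs", {
  w <- matrix(0, 3, 3)
  w[upper.tri(w)] <- c(0.2, 0.4, 0.6)
  w <- w + t(w)
  expect_equal(whole_brain(w), 0.4)
  const <- matrix(0.37, 32, 32); diag(const) <- 0
  expect_equal(whole_brain(const), 0.37)
})
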