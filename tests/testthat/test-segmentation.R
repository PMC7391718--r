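rec_with_segments <- function(lengths, fs = 64, n_channels = 2) {
  cfg <- population_config(n_subjects = 1, n_channels = n_channels,
                           sampling_rate = fs, segment_lengths = lengths,
                           seed = 11)
  simulate_session(make_population(cfg)[[1]], cfg, 1)
}

test_that("epoch cutting is maximal, non-overlapping, remainder-discarding", {
  rec <- rec_with_segments(c(10, 7))
  expect_equal(n_epochs(cut_epochs(rec, 3)), 5)  # floor(10/3) + floor(7/3)
  es <- cut_epochs(rec, 3)
  expect_true(all(vapply(es$epochs, ncol, integer(1)) == 3 * 64))
  # first two epochs tile the start of segment 1 exactly
  expect_identical(cbind(es$epochs[[1]], es$epochs[[2]]),
                   rec$segments[[1]][, 1:(2 * 3 * 64)])
  # too-short segments contribute nothing
  expect_equal(n_epochs(cut_epochs(rec_with_segments(1), 2)), 0)
})

test_that("default segment mixture supports the key schemes", {
  # the constant-amount design (20 x 6 s) and the largest short-epoch
  # combination (150 x 1 s) must always be satisfiable; the most demanding
  # long-epoch combinations (e.g. 60 x 5 s = 300 s) intentionally are not,
  # mirroring per-scheme subject exclusion
  cfg <- population_config(n_subjects = 1, n_channels = 2, sampling_rate = 64)
  rec <- simulate_session(make_population(cfg)[[1]], cfg, 1)
  expect_gte(n_epochs(cut_epochs(rec, 6)), 20)
  expect_gte(n_epochs(cut_epochs(rec, 1)), 150)
  expect_lt(n_epochs(cut_epochs(rec, 5)), 60)
})

test_that("epoch selection is uniform-without-replacement and seeded", {
  es <- cut_epochs(rec_with_segments(100), 1)
  s1 <- sample_epochs(es, 60, seed = 1)
  s2 <- sample_epochs(es, 60, seed = 1)
  expect_identical(s1$epochs, s2$epochs)
  expect_equal(n_epochs(s1), 60)
  s3 <- sample_epochs(es, 60, seed = 2)
  expect_false(identical(attr(s1, "selected_indices"),
                         attr(s3, "selected_indices")))
  expect_equal(anyDuplicated(attr(s1, "selected_indices")), 0L)
  # selecting everything keeps all epochs
  all_sel <- sample_epochs(es, n_epochs(es), seed = 3)
  expect_setequal(attr(all_sel, "selected_indices"), seq_len(n_epochs(es)))
  expect_error(sample_epochs(es, n_epochs(es) + 1, seed = 1),
               "insufficient data")
})

test_that("nested re-segmentation partitions the 6-s parents exactly", {
  es6 <- sample_epochs(cut_epochs(rec_with_segments(c(60, 66)), 6), 20,
                       seed = 4)
  for (len in c(1, 2, 3)) {
    sub <- nested_resegment(es6, len)
    expect_equal(n_epochs(sub), 20 * 6 / len)
    expect_equal(sub$epoch_length, len)
    # concatenating the first parent's children reproduces the parent
    per <- 6 / len
    expect_identical(do.call(cbind, sub$epochs[seq_len(per)]),
                     es6$epochs[[1]])
    # conservation of total sample count
    expect_equal(sum(vapply(sub$epochs, ncol, integer(1))),
                 sum(vapply(es6$epochs, ncol, integer(1))))
  }
  expect_error(nested_resegment(es6, 4), "divide")
  es2 <- nested_resegment(es6, 2)
  expect_error(nested_resegment(es2, 1), "6-s parent")
})

test_that("scheme tables match the three designs", {
  sch <- segmentation_schemes("all")
  long <- dplyr::filter(sch, approach == "long_epochs")
  expect_equal(nrow(long), 25)
  expect_setequal(long$n_epochs, c(20, 30, 40, 50, 60))
  expect_setequal(long$epoch_length, 1:5)
  short <- dplyr::filter(sch, approach == "short_epochs")
  expect_equal(nrow(short), 10)
  expect_setequal(short$n_epochs, c(30, 60, 90, 120, 150))
  const <- dplyr::filter(sch, approach == "constant_amount")
  expect_equal(const$n_epochs * const$epoch_length, rep(120, 4))
  expect_setequal(const$n_epochs, c(120, 60, 40, 20))
  expect_error(segmentation_schemes("bogus"), "unknown approach")
})
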