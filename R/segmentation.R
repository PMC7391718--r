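#' Cut a recording's clean segments into fixed-length epochs
#'
#' Each clean segment is cut into the maximal number of whole, non-overlapping
#' epochs starting from the segment's first sample; remainder samples at the
#' end of a segment are discarded. A recording with no segment long enough
#' yields an empty epoch set (the caller decides about subject exclusion).
#'
#' @param recording A `"continuous_recording"`.
#' @param epoch_length Epoch duration in seconds (> 0); must correspond to a
#'   whole number of samples.
#' @return An `"epoch_set"`: list with `subject_id`, `session_id`,
#'   `epoch_length`, `epochs` (list of channels x samples matrices),
#'   `sampling_rate`, `selection_seed` (`NA` until [sample_epochs()]).
#' @examples
#' cfg <- population_config(n_subjects = 1, n_channels = 4, sampling_rate = 64,
#'                          segment_lengths = c(10, 7))
#' rec <- simulate_session(make_population(cfg)[[1]], cfg, 1)
#' n_epochs(cut_epochs(rec, 3))  # floor(10/3) + floor(7/3) = 5
#' @export
cut_epochs <- function(recording, epoch_length) {
  stopifnot(inherits(recording, "continuous_recording"))
  check_scalar_number(epoch_length, "epoch_length", min = 0, strict_min = TRUE)
  fs <- recording$sampling_rate
  ns <- epoch_length * fs
  if (abs(ns - round(ns)) > 1e-8)
    stop_config("epoch_length %g s is not a whole number of samples at %g Hz",
                epoch_length, fs)
  ns <- as.integer(round(ns))
  epochs <- list()
  for (seg in recording$segments) {
    k <- ncol(seg) %/% ns
    if (k < 1) next
    for (i in seq_len(k))
      epochs[[length(epochs) + 1L]] <- seg[, ((i - 1L) * ns + 1L):(i * ns),
                                           drop = FALSE]
  }
  new_epoch_set(recording$subject_id, recording$session_id, epoch_length,
                epochs, fs)
}

new_epoch_set <- function(subject_id, session_id, epoch_length, epochs,
                          sampling_rate, selection_seed = NA_integer_) {
  structure(list(subject_id = subject_id, session_id = session_id,
                 epoch_length = epoch_length, epochs = epochs,
                 sampling_rate = sampling_rate,
                 selection_seed = selection_seed),
            class = "epoch_set")
}

#' Number of epochs in an epoch set
#' @param epoch_set An `"epoch_set"`.
#' @return Integer count.
#' @export
n_epochs <- function(epoch_set) length(epoch_set$epochs)

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s session %s: %d epochs of %g s @ %g Hz\n",
              x$subject_id, x$session_id, n_epochs(x), x$epoch_length,
              x$sampling_rate))
  invisible(x)
}

#' Randomly select a fixed number of epochs
#'
#' Uniform sampling without replacement, reproducible from `seed`. The
#' epoch-selection stream is independent of the data-generation stream.
#' Requesting exactly the available count returns all epochs.
#'
#' @param epoch_set An `"epoch_set"`.
#' @param n_select Number of epochs to keep.
#' @param seed Integer seed for the selection.
#' @return An `"epoch_set"` with `n_select` epochs (original order of the
#'   drawn indices) and `selection_seed` recorded.
#' @examples
#' cfg <- population_config(n_subjects = 1, n_channels = 2, sampling_rate = 64,
#'                          segment_lengths = c(10))
#' es <- cut_epochs(simulate_session(make_population(cfg)[[1]], cfg, 1), 1)
#' n_epochs(sample_epochs(es, 5, seed = 42))
#' @export
sample_epochs <- function(epoch_set, n_select, seed) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  check_scalar_number(n_select, "n_select", min = 1)
  avail <- n_epochs(epoch_set)
  if (avail < n_select)
    stop_config("insufficient data: %d epochs available, %d requested",
                avail, n_select)
  idx <- with_seed(seed, sample.int(avail, n_select))
  out <- new_epoch_set(epoch_set$subject_id, epoch_set$session_id,
                       epoch_set$epoch_length, epoch_set$epochs[idx],
                       epoch_set$sampling_rate, as.integer(seed))
  attr(out, "selected_indices") <- idx
  out
}

#' Re-segment selected 6-s epochs into shorter epochs
#'
#' Implements the constant-total-data design: the same randomly selected 6-s
#' parent epochs are cut into contiguous 1-, 2-, or 3-s sub-epochs, so every
#' epoch-length condition of that design is computed on identical underlying
#' samples. Output order preserves parent order, then within-parent order,
#' and concatenating the sub-epochs reproduces each parent exactly.
#'
#' @param six_second_set An `"epoch_set"` with `epoch_length = 6`.
#' @param target_length Target sub-epoch duration: 1, 2, or 3 seconds.
#' @return An `"epoch_set"` of the sub-epochs.
#' @examples
#' cfg <- population_config(n_subjects = 1, n_channels = 2, sampling_rate = 64,
#'                          segment_lengths = c(30))
#' es6 <- cut_epochs(simulate_session(make_population(cfg)[[1]], cfg, 1), 6)
#' n_epochs(nested_resegment(es6, 2))  # 5 parents -> 15 two-second epochs
#' @export
nested_resegment <- function(six_second_set, target_length) {
  stopifnot(inherits(six_second_set, "epoch_set"))
  if (six_second_set$epoch_length != 6)
    stop_config("nested_resegment expects 6-s parent epochs, got %g s",
                six_second_set$epoch_length)
  if (!target_length %in% c(1, 2, 3))
    stop_config("target_length must divide 6 s (1, 2, or 3)")
  ns <- as.integer(round(target_length * six_second_set$sampling_rate))
  per_parent <- 6 / target_length
  subs <- list()
  for (parent in six_second_set$epochs) {
    for (i in seq_len(per_parent))
      subs[[length(subs) + 1L]] <- parent[, ((i - 1L) * ns + 1L):(i * ns),
                                          drop = FALSE]
  }
  new_epoch_set(six_second_set$subject_id, six_second_set$session_id,
                target_length, subs, six_second_set$sampling_rate,
                six_second_set$selection_seed)
}

#' Epoch-selection schemes of the three segmentation designs
#'
#' Returns the (epoch number x epoch length) combinations of the three
#' designs: `"long_epochs"` (20-60 epochs of 1-5 s), `"short_epochs"`
#' (30-150 epochs of 1-2 s), and `"constant_amount"` (120 x 1 s, 60 x 2 s,
#' 40 x 3 s, 20 x 6 s — each 120 s of data, re-cut from the same twenty
#' 6-s parents).
#'
#' @param approach One or more of `"long_epochs"`, `"short_epochs"`,
#'   `"constant_amount"`, or `"all"`.
#' @return A tibble with columns `approach`, `n_epochs`, `epoch_length`.
#' @examples
#' segmentation_schemes("constant_amount")
#' @export
segmentation_schemes <- function(approach = "all") {
  all_schemes <- dplyr::bind_rows(
    tidyr::expand_grid(approach = "long_epochs",
                       n_epochs = c(20L, 30L, 40L, 50L, 60L),
                       epoch_length = 1:5),
    tidyr::expand_grid(approach = "short_epochs",
                       n_epochs = c(30L, 60L, 90L, 120L, 150L),
                       epoch_length = 1:2),
    tibble::tibble(approach = "constant_amount",
                   n_epochs = c(120L, 60L, 40L, 20L),
                   epoch_length = c(1, 2, 3, 6))
  )
  if (identical(approach, "all")) return(all_schemes)
  bad <- setdiff(approach, unique(all_schemes$approach))
  if (length(bad))
    stop_config("unknown approach: %s", paste(bad, collapse = ", "))
  dplyr::filter(all_schemes, .data$approach %in% !!approach)
}
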