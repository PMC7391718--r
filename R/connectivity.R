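# Spectral estimation and phase-lag connectivity (PLI, WPLI, dbWPLI).

#' Hanning-tapered Fourier coefficients of an epoch set
#'
#' Each epoch is demeaned per channel, multiplied by a periodic Hanning
#' window, and Fourier transformed (one taper per epoch). Coefficients up to
#' the Nyquist bin are kept; the bin spacing is `1 / epoch_length` Hz, so 1-s
#' epochs give 1 Hz resolution and a 6-8 Hz band covers bins {6, 7, 8}.
#'
#' @param epoch_set An `"epoch_set"` with at least one epoch; all epochs have
#'   the same length.
#' @return A `"spectral_coefficients"` object: complex array
#'   `[epoch, channel, bin]`, with `bin_frequencies` (Hz), `epoch_length`,
#'   `n_epochs`, `sampling_rate`.
#' @examples
#' cfg <- population_config(n_subjects = 1, n_channels = 2, sampling_rate = 64,
#'                          segment_lengths = c(8))
#' es <- cut_epochs(simulate_session(make_population(cfg)[[1]], cfg, 1), 1)
#' sc <- fourier_coefficients(es)
#' sc$bin_frequencies[1:5]
#' @export
fourier_coefficients <- function(epoch_set) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  ne <- n_epochs(epoch_set)
  if (ne == 0) stop_config("epoch set is empty")
  ns <- unique(vapply(epoch_set$epochs, ncol, integer(1)))
  if (length(ns) != 1) stop_config("all epochs must have the same length")
  nc <- nrow(epoch_set$epochs[[1]])
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ns) - 1) / ns)
  nbin <- ns %/% 2 + 1
  coeffs <- array(complex(real = 0), dim = c(ne, nc, nbin))
  for (e in seq_len(ne)) {
    x <- epoch_set$epochs[[e]]
    x <- x - rowMeans(x)
    f <- stats::mvfft(taper * t(x))  # ns x nc
    coeffs[e, , ] <- t(f[seq_len(nbin), , drop = FALSE])
  }
  structure(list(coefficients = coeffs,
                 bin_frequencies = (seq_len(nbin) - 1) / epoch_set$epoch_length,
                 epoch_length = epoch_set$epoch_length,
                 n_epochs = ne,
                 n_channels = nc,
                 sampling_rate = epoch_set$sampling_rate,
                 subject_id = epoch_set$subject_id,
                 session_id = epoch_set$session_id),
            class = "spectral_coefficients")
}

#' @export
print.spectral_coefficients <- function(x, ...) {
  cat(sprintf(
    "<spectral_coefficients> %d epochs x %d channels x %d bins (%g Hz spacing)\n",
    x$n_epochs, x$n_channels, length(x$bin_frequencies),
    1 / x$epoch_length))
  invisible(x)
}

band_bin_indices <- function(coeffs, band) {
  if (length(band) != 2 || band[1] > band[2])
    stop_config("band must be c(low, high) in Hz")
  idx <- which(coeffs$bin_frequencies >= band[1] - 1e-9 &
               coeffs$bin_frequencies <= band[2] + 1e-9)
  if (!length(idx))
    stop_config("no frequency bins inside the %g-%g Hz band (spacing %g Hz)",
                band[1], band[2], 1 / coeffs$epoch_length)
  idx
}

# Per-bin epoch sums of f(Im{X_ij}) for f in {sign, identity, abs, square};
# Im{X_ij} per epoch is Im(z_i) Re(z_j) - Re(z_i) Im(z_j).
imag_cross_sums <- function(z) {
  re <- Re(z); im <- Im(z)
  nc <- ncol(z)
  s_sgn <- s_sum <- s_abs <- s_sq <- matrix(0, nc, nc)
  for (i in seq_len(nc)) {
    m <- im[, i] * re - re[, i] * im  # epochs x channels: Im{X_i.}
    s_sgn[i, ] <- colSums(sign(m))
    s_sum[i, ] <- colSums(m)
    s_abs[i, ] <- colSums(abs(m))
    s_sq[i, ]  <- colSums(m * m)
  }
  list(sgn = s_sgn, sum = s_sum, abs = s_abs, sq = s_sq)
}

new_connectivity_matrix <- function(weights, method, band, n_epochs_used) {
  diag(weights) <- 0
  dimnames(weights) <- list(channel_names(nrow(weights)),
                            channel_names(nrow(weights)))
  structure(list(weights = weights, method = method, band = band,
                 n_epochs_used = n_epochs_used),
            class = "connectivity_matrix")
}

channel_names <- function(n) sprintf("ch%02d", seq_len(n))

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, %g-%g Hz, %d channels, %d epochs\n",
              x$method, x$band[1], x$band[2], nrow(x$weights),
              x$n_epochs_used))
  cat(sprintf("  whole-brain mean %.4f, range [%.4f, %.4f]\n",
              whole_brain(x), min(x$weights[upper.tri(x$weights)]),
              max(x$weights[upper.tri(x$weights)])))
  invisible(x)
}

connectivity_by_bin <- function(coeffs, band, fun) {
  idx <- band_bin_indices(coeffs, band)
  mats <- lapply(idx, function(b) {
    z <- coeffs$coefficients[, , b, drop = FALSE]
    dim(z) <- dim(z)[1:2]
    fun(z)
  })
  Reduce(`+`, mats) / length(mats)
}

#' Phase lag index (PLI) connectivity matrix
#'
#' For each channel pair and frequency bin, the PLI is the absolute mean over
#' epochs of the sign of the imaginary cross-spectrum,
#' \eqn{\mathrm{PLI} = |E\{\mathrm{sgn}(\Im\{X\})\}|}, with `sgn(0)`
#' contributing 0. Per-bin matrices are averaged over all bins inside the
#' (inclusive) band. PLI lies in `[0, 1]`; it is insensitive to zero-lag
#' (volume-conduction) coupling but positively biased at small epoch counts.
#'
#' @param coeffs A `"spectral_coefficients"` object.
#' @param band Frequency band `c(low, high)` in Hz; default 6-8 Hz.
#' @return A `"connectivity_matrix"` (symmetric, zero diagonal).
#' @examples
#' cfg <- population_config(n_subjects = 1, n_channels = 4, sampling_rate = 64,
#'                          segment_lengths = c(30))
#' es <- cut_epochs(simulate_session(make_population(cfg)[[1]], cfg, 1), 1)
#' pli_matrix(fourier_coefficients(es))
#' @export
pli_matrix <- function(coeffs, band = c(6, 8)) {
  stopifnot(inherits(coeffs, "spectral_coefficients"))
  w <- connectivity_by_bin(coeffs, band, function(z) {
    abs(imag_cross_sums(z)$sgn) / nrow(z)
  })
  new_connectivity_matrix(w, "PLI", band, coeffs$n_epochs)
}

#' Weighted phase lag index (WPLI) connectivity matrix
#'
#' The magnitude-weighted variant of the PLI:
#' \eqn{\mathrm{WPLI} = |E\{\Im\{X\}\}| / E\{|\Im\{X\}|\}} per bin, averaged
#' over the band. Pairs whose imaginary cross-spectrum is identically zero
#' get 0. Like the PLI this estimator is positively biased at small epoch
#' counts; see [dbwpli_matrix()] for the debiased version.
#'
#' @inheritParams pli_matrix
#' @return A `"connectivity_matrix"`.
#' @export
wpli_matrix <- function(coeffs, band = c(6, 8)) {
  stopifnot(inherits(coeffs, "spectral_coefficients"))
  w <- connectivity_by_bin(coeffs, band, function(z) {
    s <- imag_cross_sums(z)
    out <- abs(s$sum) / s$abs
    out[s$abs == 0] <- 0
    out
  })
  new_connectivity_matrix(w, "WPLI", band, coeffs$n_epochs)
}

#' Debiased weighted phase lag index (dbWPLI) connectivity matrix
#'
#' The debiased WPLI-square estimator built from pairwise products of
#' distinct epochs: with \eqn{I_e = \Im\{X_e\}} the per-epoch imaginary
#' cross-spectrum,
#' \deqn{\mathrm{dbWPLI} = \frac{(\sum_e I_e)^2 - \sum_e I_e^2}
#'                              {(\sum_e |I_e|)^2 - \sum_e I_e^2},}
#' per bin, then averaged over the band. The numerator/denominator structure
#' cancels the small-sample inflation of the PLI/WPLI, so under independence
#' its expectation is ~0 regardless of the number of epochs. Values lie in
#' `[-1, 1]`; a degenerate denominator (fewer than two non-zero epochs)
#' yields 0. Requires at least 2 epochs.
#'
#' @inheritParams pli_matrix
#' @return A `"connectivity_matrix"`.
#' @examples
#' cfg <- population_config(n_subjects = 1, n_channels = 4, sampling_rate = 64,
#'                          segment_lengths = c(30))
#' es <- cut_epochs(simulate_session(make_population(cfg)[[1]], cfg, 1), 1)
#' dbwpli_matrix(fourier_coefficients(es))
#' @export
dbwpli_matrix <- function(coeffs, band = c(6, 8)) {
  stopifnot(inherits(coeffs, "spectral_coefficients"))
  if (coeffs$n_epochs < 2)
    stop_config("dbWPLI debiasing requires at least 2 epochs")
  w <- connectivity_by_bin(coeffs, band, function(z) {
    s <- imag_cross_sums(z)
    num <- s$sum^2 - s$sq
    den <- s$abs^2 - s$sq
    out <- num / den
    out[den <= 0] <- 0
    out
  })
  new_connectivity_matrix(w, "dbWPLI", band, coeffs$n_epochs)
}

#' Whole-brain connectivity
#'
#' The mean connectivity across all distinct channel pairs (strict upper
#' triangle). For the dbWPLI the signed values are averaged; absolute values
#' enter only the graph metrics.
#'
#' @param matrix A `"connectivity_matrix"` or plain symmetric matrix.
#' @return A single number.
#' @examples
#' m <- matrix(c(0, .2, .4, .2, 0, .6, .4, .6, 0), 3)
#' whole_brain(m)  # 0.4
#' @export
whole_brain <- function(matrix) {
  w <- if (inherits(matrix, "connectivity_matrix")) matrix$weights else matrix
  check_square_symmetric(w)
  mean(w[upper.tri(w)])
}
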