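# Independent oracles and fixture builders used across the suite.
# Oracles deliberately use different algorithms/code paths than the package.

# Onnela weighted clustering by explicit triple-loop triangle enumeration
brute_force_clustering <- function(w) {
  n <- nrow(w)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    t_i <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h)
          t_i <- t_i + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
      }
    }
    ci[i] <- t_i / (k * (k - 1))  # t_i double-counts ordered (j,h) = 2 t
  }
  mean(ci)
}

# all-pairs shortest paths by Floyd-Warshall on inverse-weight lengths
floyd_warshall_path_length <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      dk <- d[i, k] + d[k, ]
      shorter <- dk < d[i, ]
      d[i, shorter] <- dk[shorter]
    }
  }
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

# ICC(3,1) machinery from R's own two-way ANOVA fit
aov_icc <- function(df) {
  fit <- stats::aov(value ~ factor(subject_id) + factor(session_id), data = df)
  tab <- summary(fit)[[1]]
  ms_r <- tab["factor(subject_id)", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  k <- length(unique(df$session_id))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
}

# random dense-ish symmetric weight matrix with some zero edges
random_weight_matrix <- function(n, p_zero = 0.2) {
  w <- matrix(0, n, n)
  iu <- which(upper.tri(w))
  vals <- stats::runif(length(iu))
  vals[stats::runif(length(iu)) < p_zero] <- 0
  w[iu] <- vals
  w + t(w)
}

# spectral_coefficients built directly from a complex array [epoch, ch, bin]
make_coeffs <- function(z, bin_frequencies, epoch_length = 1) {
  structure(list(coefficients = z,
                 bin_frequencies = bin_frequencies,
                 epoch_length = epoch_length,
                 n_epochs = dim(z)[1],
                 n_channels = dim(z)[2],
                 sampling_rate = NA_real_,
                 subject_id = "T001", session_id = 1),
            class = "spectral_coefficients")
}

# independent complex-Gaussian coefficients at one 7 Hz bin
gaussian_coeffs <- function(n_epochs, n_channels) {
  z <- array(complex(real = stats::rnorm(n_epochs * n_channels),
                     imaginary = stats::rnorm(n_epochs * n_channels)),
             dim = c(n_epochs, n_channels, 1))
  make_coeffs(z, bin_frequencies = 7)
}

with_seed_for_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

# small study configuration used by pipeline tests
tiny_config <- function(...) {
  population_config(n_subjects = 6, n_channels = 8, sampling_rate = 64,
                    segment_lengths = c(20, 16), seed = 7, ...)
}
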