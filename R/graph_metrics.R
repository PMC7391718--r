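# Weighted graph metrics and surrogate normalisation.
# Inputs are non-negative symmetric weight matrices (PLI, or |dbWPLI|).

as_weight_matrix <- function(matrix, absolute = FALSE) {
  w <- if (inherits(matrix, "connectivity_matrix")) matrix$weights else matrix
  if (absolute) w <- abs(w)
  check_square_symmetric(w)
  if (any(w < 0))
    stop_config("graph metrics need non-negative weights; take abs() first")
  diag(w) <- 0
  w
}

#' Rescale connection weights to a unit maximum
#'
#' Divides all weights by the maximum weight, the conventional preparation
#' before the weighted clustering coefficient so that triangle intensities
#' are comparable across matrices. An all-zero matrix is returned unchanged;
#' a matrix whose maximum is already 1 is a fixed point.
#'
#' @param matrix Non-negative symmetric weight matrix (or
#'   `"connectivity_matrix"`).
#' @return A plain weight matrix with maximum 1 (or all zeros).
#' @examples
#' rescale_weights(matrix(c(0, .2, .2, 0), 2))
#' @export
rescale_weights <- function(matrix) {
  w <- as_weight_matrix(matrix)
  m <- max(w)
  if (m == 0) w else w / m
}

#' Weighted clustering coefficient
#'
#' Mean over nodes of the weighted triangle intensity around each node
#' (geometric-mean / Onnela convention: the cube root of the product of the
#' three rescaled edge weights, summed over triangles), divided by the number
#' of possible triangles \eqn{k_i (k_i - 1) / 2} given the node's degree
#' \eqn{k_i} (count of non-zero-weight neighbours). Nodes of degree < 2
#' contribute 0. Expects weights already rescaled to a unit maximum
#' ([rescale_weights()]).
#'
#' @param matrix Rescaled non-negative symmetric weight matrix (or
#'   `"connectivity_matrix"`).
#' @return The average weighted clustering coefficient, in `[0, 1]`.
#' @examples
#' w <- matrix(1, 4, 4) - diag(4)
#' weighted_clustering(w)  # complete unit-weight graph: 1
#' @export
weighted_clustering <- function(matrix) {
  w <- as_weight_matrix(matrix)
  w3 <- w^(1 / 3)
  two_t <- diag(w3 %*% w3 %*% w3)  # 2 * triangle intensity per node
  k <- rowSums(w > 0)
  ci <- ifelse(k < 2, 0, two_t / (k * (k - 1)))
  mean(ci)
}

#' Weighted characteristic path length
#'
#' Edge lengths are inverse weights (zero weight = no edge); shortest paths
#' are computed over these lengths (Dijkstra via \pkg{igraph}) and averaged
#' over all ordered node pairs: \eqn{L^w = \frac{1}{n}\sum_i
#' \frac{\sum_{j \ne i} d^w_{ij}}{n - 1}}. Disconnected pairs (never expected
#' for dense phase-lag matrices) are dropped from each node's average with a
#' warning.
#'
#' @param matrix Non-negative symmetric weight matrix (or
#'   `"connectivity_matrix"`).
#' @return The characteristic path length (positive; `NaN` for an edgeless
#'   matrix).
#' @examples
#' weighted_path_length(matrix(c(0, .5, .5, 0), 2))  # 1 / 0.5 = 2
#' @export
weighted_path_length <- function(matrix) {
  w <- as_weight_matrix(matrix)
  n <- nrow(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                         algorithm = "dijkstra")
  off <- d[row(d) != col(d)]
  if (any(is.infinite(off))) {
    warning("disconnected node pairs excluded from the path-length average")
    per_node <- apply(d, 1, function(r) {
      r <- r[is.finite(r) & r > 0]
      if (length(r)) mean(r) else NA_real_
    })
    return(mean(per_node, na.rm = TRUE))
  }
  mean(matrix(d[row(d) != col(d)], nrow = n))
}

# surrogate null: permute the strict-upper-triangle weights uniformly and
# mirror back to symmetry (preserves the weight distribution, randomises
# topology)
surrogate_matrix <- function(w) {
  n <- nrow(w)
  iu <- upper_pairs(n)
  s <- matrix(0, n, n)
  s[iu] <- sample(w[iu])
  s + t(s)
}

#' Surrogate-normalised graph metrics and small-worldness
#'
#' Computes the weighted clustering coefficient \eqn{C^w} and characteristic
#' path length \eqn{L^w} of a (rescaled) weight matrix, normalises each by
#' its mean over `n_surrogates` surrogate matrices — random permutations of
#' the upper-triangle weights, preserving the weight distribution while
#' randomising topology — and forms the small-worldness index
#' \eqn{\mathrm{SWI} = C^w_{norm} / L^w_{norm}}. Deterministic given `seed`.
#'
#' @param matrix Non-negative symmetric weight matrix or
#'   `"connectivity_matrix"` (take `abs()` of dbWPLI weights first, or use
#'   `absolute = TRUE`).
#' @param n_surrogates Number of surrogate matrices (default 1000, as used
#'   for the reference analysis; reduce for quick exploration).
#' @param seed Integer seed for the surrogate stream.
#' @param absolute Take absolute weights first (for signed dbWPLI matrices).
#' @return A `"graph_metric_set"`: list with `C_w`, `C_w_norm`, `L_w`,
#'   `L_w_norm`, `SWI`, surrogate means/SDs, `n_surrogates`,
#'   `surrogate_seed`.
#' @examples
#' w <- rescale_weights(matrix(runif(64), 8, 8) |> (\(m) (m + t(m)) / 2)())
#' surrogate_normalise(w, n_surrogates = 20, seed = 1)
#' @export
surrogate_normalise <- function(matrix, n_surrogates = 1000, seed = 1L,
                                absolute = FALSE) {
  check_scalar_number(n_surrogates, "n_surrogates", min = 1)
  w <- rescale_weights(as_weight_matrix(matrix, absolute = absolute))
  c_obs <- weighted_clustering(w)
  l_obs <- weighted_path_length(w)
  cs <- ls_ <- numeric(n_surrogates)
  with_seed(seed, {
    for (b in seq_len(n_surrogates)) {
      s <- surrogate_matrix(w)
      cs[b] <- weighted_clustering(s)
      ls_[b] <- weighted_path_length(s)
    }
  })
  c_rand <- mean(cs); l_rand <- mean(ls_)
  if (c_rand == 0 || l_rand == 0 || !is.finite(c_rand) || !is.finite(l_rand))
    stop_config("degenerate matrix: surrogate mean clustering/path length is 0")
  structure(list(
    C_w = c_obs, C_w_norm = c_obs / c_rand,
    L_w = l_obs, L_w_norm = l_obs / l_rand,
    SWI = (c_obs / c_rand) / (l_obs / l_rand),
    C_w_rand = c_rand, L_w_rand = l_rand,
    C_w_rand_sd = stats::sd(cs), L_w_rand_sd = stats::sd(ls_),
    n_surrogates = as.integer(n_surrogates),
    surrogate_seed = as.integer(seed)
  ), class = "graph_metric_set")
}

#' @export
print.graph_metric_set <- function(x, ...) {
  cat(sprintf(paste0(
    "<graph_metric_set> C_w %.4f (norm %.4f), L_w %.4f (norm %.4f), ",
    "SWI %.4f [%d surrogates]\n"),
    x$C_w, x$C_w_norm, x$L_w, x$L_w_norm, x$SWI, x$n_surrogates))
  invisible(x)
}
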