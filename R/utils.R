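# internal helpers: seed substreams, seeded evaluation, validation

MERSENNE31 <- 2147483647

#' Derive a reproducible substream seed
#'
#' Expands one global seed into independent per-context seeds (per subject,
#' session, epoch-selection call, surrogate draw, ...) by mixing integer and
#' character keys through a multiplicative-congruential hash. The mixing stays
#' below 2^53 so arithmetic is exact in doubles, and the result is a positive
#' 32-bit integer usable with [set.seed()].
#'
#' @param seed Integer global seed.
#' @param ... Integer or character keys identifying the substream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' substream_seed(1, "subject", 7, "session", 2)
#' @export
substream_seed <- function(seed, ...) {
  keys <- list(...)
  s <- (abs(as.numeric(seed)) + 1) %% MERSENNE31
  step <- function(s, k) ((s * 48271) %% MERSENNE31 + k + 1) %% MERSENNE31
  for (key in keys) {
    if (is.character(key)) {
      for (k in utf8ToInt(paste(key, collapse = "|"))) s <- step(s, k)
    } else if (is.numeric(key)) {
      for (k in as.numeric(key)) s <- step(s, abs(k) %% MERSENNE31)
    } else {
      stop("substream keys must be numeric or character", call. = FALSE)
    }
  }
  # final scramble so trailing zero keys do not collide
  s <- step(s, 104729)
  as.integer(s %% (MERSENNE31 - 2) + 1)
}

# evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop_config("`%s` must be a single finite number", name)
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok)
    stop_config("`%s` = %g is outside its allowed range", name, x)
  invisible(x)
}

check_square_symmetric <- function(w, name = "weights", tol = 1e-10) {
  if (!is.matrix(w) || nrow(w) != ncol(w))
    stop_config("`%s` must be a square matrix", name)
  if (max(abs(w - t(w))) > tol)
    stop_config("`%s` must be symmetric", name)
  invisible(w)
}

upper_pairs <- function(n) which(upper.tri(matrix(0, n, n)))

# clip into [lo, hi]
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)
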