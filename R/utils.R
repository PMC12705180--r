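# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Dirichlet draw via normalized gammas; alpha is a concentration vector.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  sums <- rowSums(x)
  # all-zero rows (tiny alpha underflow) fall back to uniform
  zero <- sums <= 0
  if (any(zero)) {
    x[zero, ] <- 1
    sums[zero] <- k
  }
  x / sums
}

# Trailing moving average: value at position i is mean(x[(i-window+1):i]),
# NA until a full window exists. No lookahead.
trailing_mean <- function(x, window) {
  n <- length(x)
  if (window < 1L) abort("`window` must be >= 1.")
  out <- rep(NA_real_, n)
  if (n >= window) {
    cs <- cumsum(x)
    out[window:n] <- (cs[window:n] - c(0, cs)[(window:n) - window + 1L]) / window
  }
  out
}

# Cosine similarity between two numeric vectors; 0 when either has zero norm.
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Row L2-normalization of a (possibly sparse) matrix; zero rows left as zero.
l2_normalize_rows <- function(m) {
  norms <- sqrt(Matrix::rowSums(m^2))
  norms[norms == 0] <- 1
  Matrix::Diagonal(x = 1 / norms) %*% m
}

# argmax with ties broken toward the lowest index
which_max_first <- function(x) which.max(x)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
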