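# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive double loops / grid searches, kept separate from the
# implementation paths they check.

oracle_sq_dist <- function(Y) {
  N <- nrow(Y)
  D <- matrix(0, N, N)
  for (n in seq_len(N)) {
    for (m in seq_len(N)) {
      D[n, m] <- sum((Y[n, ] - Y[m, ])^2)
    }
  }
  D
}

# Energy by explicit double loop over ordered pairs (m, n).
oracle_energy <- function(X, w_p, w_n, lambda, temporal = NULL, beta = 0) {
  N <- nrow(X)
  E <- 0
  for (m in seq_len(N)) {
    for (n in seq_len(N)) {
      d2 <- sum((X[n, ] - X[m, ])^2)
      rep_w <- w_n[n, m] + if (!is.null(temporal)) beta * temporal[n, m] else 0
      E <- E + w_p[n, m] * d2 + lambda * rep_w * exp(-d2)
    }
  }
  E
}

# Perplexity of the conditional distribution at a given sigma, computed the
# long way (explicit probabilities, entropy in bits).
oracle_perplexity <- function(off, sigma) {
  p <- exp(-off / (2 * sigma^2))
  p <- p / sum(p)
  nz <- p > 0
  2^(-sum(p[nz] * log2(p[nz])))
}

# Sigma root by coarse grid scan followed by plain bisection on sigma itself
# (not log-sigma), independent of the package solver.
oracle_sigma <- function(off, perplexity) {
  grid <- 10^seq(-6, 6, length.out = 2000)
  vals <- vapply(grid, function(s) oracle_perplexity(off, s), numeric(1))
  i <- which(vals >= perplexity)[1]
  stopifnot(!is.na(i), i > 1)
  lo <- grid[i - 1]; hi <- grid[i]
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (oracle_perplexity(off, mid) >= perplexity) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Quadratic form of the graph Laplacian via the pairwise identity
# x' L x = (1/2) sum_{m,n} w_mn (x_m - x_n)^2.
oracle_laplacian_quadform <- function(W, x) {
  N <- length(x)
  q <- 0
  for (m in seq_len(N)) {
    for (n in seq_len(N)) {
      q <- q + W[m, n] * (x[m] - x[n])^2
    }
  }
  q / 2
}

# Tiny affinity model with hand-set weights (two-point and toy cases).
toy_model <- function(w_p, w_n, temporal = NULL, perplexity = 2) {
  structure(
    list(w_p = w_p, w_n = w_n, sigma = rep(1, nrow(w_p)),
         perplexity = perplexity, temporal = temporal, n = nrow(w_p)),
    class = "ee_affinity"
  )
}

# Fraction of points whose nearest neighbor (in rows of X, excluding self)
# carries the same label.
knn1_agreement <- function(X, labels) {
  D <- oracle_sq_dist(X)
  diag(D) <- Inf
  mean(labels[apply(D, 1, which.min)] == labels)
}
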