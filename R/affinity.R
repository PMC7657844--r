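# Pairwise affinity construction: squared distances, perplexity-calibrated
# attractive weights, repulsive weights, optional temporal dissimilarities.

#' Pairwise squared Euclidean distances
#'
#' Computes the dense \eqn{N \times N} matrix of squared Euclidean distances
#' between the rows of a sample-by-feature matrix. The squared distance is
#' the quantity both weight families consume: the repulsive weight is the
#' squared distance itself and the attractive weight exponentiates it, so a
#' single computation feeds both.
#'
#' @param Y numeric matrix, \eqn{N} samples in rows, features in columns.
#'   All entries must be finite.
#' @return symmetric \eqn{N \times N} matrix with zero diagonal and
#'   non-negative entries (negative round-off is clamped to zero).
#' @examples
#' pairwise_sq_dist(matrix(c(0, 3), ncol = 1))
#' @export
pairwise_sq_dist <- function(Y) {
  Y <- as_data_matrix(Y)
  rs <- rowSums(Y * Y)
  D <- outer(rs, rs, "+") - 2 * tcrossprod(Y)
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

# Block-row variant: squared distances from rows `rows` of Y to all rows.
# When the block covers every row this delegates to pairwise_sq_dist() so a
# single-worker run is bitwise identical to the serial path.
cross_sq_dist <- function(Y, rows) {
  n <- nrow(Y)
  if (length(rows) == n && all(rows == seq_len(n))) {
    return(pairwise_sq_dist(Y))
  }
  rs <- rowSums(Y * Y)
  D <- outer(rs[rows], rs, "+") - 2 * tcrossprod(Y[rows, , drop = FALSE], Y)
  D[D < 0] <- 0
  D[cbind(seq_along(rows), rows)] <- 0
  D
}

# Perplexity (2^H with entropy H in bits) of the conditional distribution
# p_m \propto exp(-off_m / (2 sigma^2)) over the off-self distances `off`.
# Computed via natural-log entropy: 2^{H_bits} = exp(H_nats), with the
# shifted-logit identity H_nats = log(S) - sum(w * s) / S for w = exp(s),
# S = sum(w) (one exp and two sums per evaluation; this is the inner loop of
# the bisection).
achieved_perplexity <- function(off, sigma) {
  s <- -off / (2 * sigma^2)
  s <- s - max(s)
  w <- exp(s)
  ws <- w * s
  if (anyNA(ws)) ws[w == 0] <- 0  # 0 * -Inf from fully underflowed logits
  S <- sum(w)
  exp(log(S) - sum(ws) / S)
}

#' Calibrate one per-sample bandwidth to a target perplexity
#'
#' Finds \eqn{\sigma > 0} such that the conditional neighbor distribution
#' \eqn{p_m \propto \exp(-D_m / (2\sigma^2))} (over \eqn{m \neq}
#' \code{self_index}) attains the target perplexity \eqn{2^{H(p)}} with
#' entropy in bits. Perplexity is monotone increasing in \eqn{\sigma}, so the
#' root is unique; it is found by bisection on \eqn{\log \sigma} after
#' geometric bracket expansion from \code{init}. The bracket is contracted to
#' essentially machine precision (width \code{1e-12} on the log scale), which
#' makes the result independent of the warm start: the initial value affects
#' speed only.
#'
#' @param D_row length-\eqn{N} non-negative squared distances (one row of the
#'   distance matrix, including the zero self entry).
#' @param self_index index of the sample itself within \code{D_row}.
#' @param perplexity target perplexity, in \eqn{(1, N-1]}.
#' @param init positive warm start for \eqn{\sigma}.
#' @param max_iter bisection iteration cap.
#' @return positive scalar \eqn{\sigma}.
#' @export
calibrate_sigma <- function(D_row, self_index, perplexity, init = 1.0,
                            max_iter = 200L) {
  N <- length(D_row)
  if (!is.numeric(perplexity) || length(perplexity) != 1L ||
      !(perplexity > 1 && perplexity <= N - 1)) {
    abort_ee(sprintf("perplexity must satisfy 1 < perplexity <= N - 1 (N = %d)", N),
             "ee_invalid_parameter")
  }
  if (!all(is.finite(D_row)) || any(D_row < 0)) {
    abort_ee("distances must be finite and non-negative", "ee_invalid_input")
  }
  off <- D_row[-self_index]
  if (all(off == 0)) {
    abort_ee("all off-self distances are zero (duplicate-degenerate row)",
             "ee_duplicate_degenerate")
  }
  if (!is.finite(init) || init <= 0) init <- 1.0

  f <- function(ls) achieved_perplexity(off, exp(ls)) - perplexity

  l0 <- log(init)
  f0 <- f(l0)
  if (abs(f0) <= 1e-12 * perplexity) {
    return(init)
  }

  # Geometric bracket expansion: perplexity is increasing in sigma.
  step <- log(2)
  if (f0 > 0) {
    hi <- l0; fhi <- f0
    lo <- l0 - step; flo <- f(lo)
    k <- 0L
    while (flo > 0 && k < 100L) {
      hi <- lo
      lo <- lo - step
      flo <- f(lo)
      k <- k + 1L
    }
    if (flo > 0) return(exp(lo))  # asymptote reached (heavy tie structure)
  } else {
    lo <- l0
    hi <- l0 + step; fhi <- f(hi)
    k <- 0L
    while (fhi < 0 && k < 100L) {
      lo <- hi
      hi <- hi + step
      fhi <- f(hi)
      k <- k + 1L
    }
    if (fhi < 0) return(exp(hi))  # perplexity ~ N-1 asymptote
  }

  iter <- 0L
  while (hi - lo > 1e-12 && iter < max_iter) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) {
      lo <- mid
      hi <- mid
      break
    }
    if (fm > 0) hi <- mid else lo <- mid
    iter <- iter + 1L
  }
  exp((lo + hi) / 2)
}

# Greedy nearest-neighbor chain over the rows of a square distance matrix:
# start at row 1, repeatedly append the unvisited row closest to the current
# one. Used to order the sigma root-finding problems so consecutive warm
# starts are maximally useful; the order affects speed only.
chain_order_from_dist <- function(Dsub) {
  m <- nrow(Dsub)
  if (m == 1L) return(1L)
  ord <- integer(m)
  visited <- logical(m)
  cur <- 1L
  ord[1L] <- 1L
  visited[1L] <- TRUE
  for (k in 2:m) {
    d <- Dsub[cur, ]
    d[visited] <- Inf
    cur <- which.min(d)
    ord[k] <- cur
    visited[cur] <- TRUE
  }
  ord
}

#' Warm-start processing order for serial sigma calibration
#'
#' @param D symmetric squared-distance matrix.
#' @return permutation of \code{1:N} (greedy nearest-neighbor chain from
#'   row 1).
#' @export
sigma_chain_order <- function(D) {
  chain_order_from_dist(D)
}

#' Calibrate all per-sample bandwidths
#'
#' Solves the \eqn{N} perplexity root-finding problems sequentially in the
#' given order, seeding each problem with the previous solution (the first
#' with 1). Rows whose off-self distances are all zero (exact duplicates of
#' every other point) get \eqn{\sigma} equal to the smallest positive normal
#' double, with a warning; such a \eqn{\sigma} reproduces the uniform
#' conditional distribution over the duplicates in the attractive weights.
#'
#' @param D symmetric \eqn{N \times N} squared-distance matrix.
#' @param perplexity target perplexity in \eqn{(1, N-1]}.
#' @param order optional permutation of \code{1:N}; defaults to the greedy
#'   nearest-neighbor chain of [sigma_chain_order()].
#' @return length-\eqn{N} vector of positive \eqn{\sigma_n}.
#' @export
calibrate_all_sigmas <- function(D, perplexity, order = NULL) {
  N <- nrow(D)
  if (is.null(order)) order <- sigma_chain_order(D)
  if (length(order) != N || !setequal(order, seq_len(N))) {
    abort_ee("`order` must be a permutation of 1:N", "ee_invalid_parameter")
  }
  sigma <- numeric(N)
  init <- 1.0
  for (n in order) {
    s <- tryCatch(
      calibrate_sigma(D[n, ], n, perplexity, init = init),
      ee_duplicate_degenerate = function(e) {
        warn_ee(sprintf("row %d duplicates every other point; sigma set to machine-tiny", n),
                "ee_degenerate_row")
        .Machine$double.xmin
      }
    )
    sigma[n] <- s
    if (s > .Machine$double.xmin) init <- s
  }
  sigma
}

#' Raw attractive weights
#'
#' \eqn{w^+_{nm} = \exp[-D_{nm} / (2\sigma_n^2)]} with the diagonal set to
#' zero. Row-asymmetric in general because \eqn{\sigma} is row-specific.
#'
#' @param D squared-distance matrix.
#' @param sigma length-\eqn{N} positive bandwidths.
#' @return \eqn{N \times N} raw weight matrix (not yet symmetrized).
#' @export
build_attractive <- function(D, sigma) {
  N <- nrow(D)
  if (length(sigma) != N || any(!is.finite(sigma)) || any(sigma <= 0)) {
    abort_ee("`sigma` must be length N and strictly positive", "ee_invalid_parameter")
  }
  W <- attractive_kernel(D, sigma)
  diag(W) <- 0
  W
}

# exp(-D / (2 sigma^2)) with sigma recycled along columns, i.e. by row
# index: entry [n, m] uses sigma[n]. sigma^2 is floored at the smallest
# positive normal double so a machine-tiny sigma (duplicate-degenerate row)
# yields exactly 1 on zero distances and 0 elsewhere instead of 0/0.
attractive_kernel <- function(D, sigma) {
  exp(-D / (2 * pmax(sigma^2, .Machine$double.xmin)))
}

#' Symmetrize and normalize a weight matrix
#'
#' Returns \eqn{(W + W^\top) / \mathrm{sum}(W + W^\top)}: symmetric, zero
#' diagonal preserved, total sum 1.
#'
#' @param W_raw non-negative matrix with zero diagonal.
#' @return symmetric matrix summing to 1.
#' @export
symmetrize_normalize <- function(W_raw) {
  if (!is.matrix(W_raw) || nrow(W_raw) != ncol(W_raw)) {
    abort_ee("`W_raw` must be square", "ee_invalid_input")
  }
  if (any(diag(W_raw) != 0)) {
    abort_ee("`W_raw` must have a zero diagonal", "ee_invalid_input")
  }
  S <- W_raw + t(W_raw)
  total <- sum(S)
  if (total <= 0) {
    abort_ee("all weights are zero; affinities are degenerate", "ee_degenerate_affinity")
  }
  S / total
}

#' Normalized repulsive weights
#'
#' The repulsive weight is the squared distance itself, normalized by the
#' total sum. The distance matrix is already symmetric with a zero diagonal,
#' so no symmetrization is needed.
#'
#' @param D squared-distance matrix.
#' @return symmetric matrix summing to 1.
#' @export
normalize_repulsive <- function(D) {
  total <- sum(D)
  if (total <= 0) {
    abort_ee("all samples are identical; repulsive weights are degenerate",
             "ee_degenerate_affinity")
  }
  D / total
}

#' Normalized temporal dissimilarities
#'
#' Builds the pairwise time-dissimilarity matrix used by the time-series
#' energy: squared differences by default (mirroring the squared repulsive
#' distances) or absolute differences, normalized to total sum 1 so the
#' \eqn{\beta} trade-off acts on the same scale as the normalized repulsive
#' weights. If all time stamps coincide an all-zero matrix is returned with a
#' warning and the time-series energy degrades to plain elastic embedding.
#'
#' @param t length-\eqn{N} finite time stamps.
#' @param n_expected optional expected \eqn{N} for length validation.
#' @param dialect "squared" (default) or "absolute".
#' @return symmetric \eqn{N \times N} matrix, zero diagonal, sum 1 (or all
#'   zero when the times are constant).
#' @export
build_temporal <- function(t, n_expected = NULL,
                           dialect = c("squared", "absolute")) {
  dialect <- match.arg(dialect)
  if (!is.numeric(t) || !all(is.finite(t))) {
    abort_ee("time stamps must be finite numerics", "ee_invalid_input")
  }
  if (!is.null(n_expected) && length(t) != n_expected) {
    abort_ee(sprintf("expected %d time stamps, got %d", n_expected, length(t)),
             "ee_invalid_input")
  }
  Tm <- outer(t, t, "-")
  Tm <- if (dialect == "squared") Tm * Tm else abs(Tm)
  diag(Tm) <- 0
  total <- sum(Tm)
  if (total <= 0) {
    warn_ee("all time stamps are identical; temporal term is zero and TSEE reduces to EE",
            "ee_constant_times")
    return(Tm)
  }
  Tm / total
}

#' Build the full affinity model for elastic embedding
#'
#' Runs the complete affinity stage: squared distances, per-sample bandwidth
#' calibration (warm-started along a nearest-neighbor chain), attractive
#' weights (symmetrized, normalized to sum 1), repulsive weights (normalized
#' squared distances), and, when time stamps are supplied, normalized
#' temporal dissimilarities.
#'
#' @param Y numeric sample-by-feature matrix (\eqn{N \ge 2}).
#' @param perplexity target perplexity (default 20).
#' @param times optional length-\eqn{N} time stamps for the time-series
#'   energy.
#' @param order optional sigma-calibration order (speed only).
#' @param temporal_dialect "squared" or "absolute" time differences.
#' @return object of class \code{ee_affinity} with fields \code{w_p},
#'   \code{w_n}, \code{sigma}, \code{perplexity}, \code{temporal}, \code{n}.
#' @examples
#' Y <- matrix(rnorm(40), 20, 2)
#' m <- ee_affinity(Y, perplexity = 5)
#' sum(m$w_p)  # 1
#' @export
ee_affinity <- function(Y, perplexity = 20, times = NULL, order = NULL,
                        temporal_dialect = c("squared", "absolute")) {
  Y <- as_data_matrix(Y)
  N <- nrow(Y)
  if (N < 2L) abort_ee("at least 2 samples are required", "ee_invalid_input")
  D <- pairwise_sq_dist(Y)
  sigma <- calibrate_all_sigmas(D, perplexity, order = order)
  w_p <- symmetrize_normalize(build_attractive(D, sigma))
  w_n <- normalize_repulsive(D)
  temporal <- if (!is.null(times)) {
    build_temporal(times, n_expected = N, dialect = match.arg(temporal_dialect))
  }
  structure(
    list(w_p = w_p, w_n = w_n, sigma = sigma, perplexity = perplexity,
         temporal = temporal, n = N),
    class = "ee_affinity"
  )
}

#' @export
print.ee_affinity <- function(x, ...) {
  cat(sprintf("Elastic-embedding affinity model: N = %d, perplexity = %g%s\n",
              x$n, x$perplexity,
              if (is.null(x$temporal)) "" else ", with temporal term"))
  invisible(x)
}
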