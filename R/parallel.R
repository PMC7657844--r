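# Row-partitioned execution of the identical algorithm: each worker owns a
# contiguous block of rows of every N x N matrix; global scalars (weight
# normalizers, energy) are formed by rank-ordered reductions of per-block
# partial sums, and N x d objects are re-assembled by an all-gather
# (rank-ordered rbind). The backend is an in-process worker loop honoring
# that dataflow: message passing is a transport detail, the contract is the
# blocks each worker touches and the reduction order.

#' Contiguous row-block partition
#'
#' Splits \code{1:N} into \code{P} contiguous blocks whose sizes differ by at
#' most one: the first \code{N \%\% P} blocks get \eqn{\lceil N/P \rceil}
#' rows, the rest \eqn{\lfloor N/P \rfloor}.
#'
#' @param N number of rows.
#' @param P number of workers, \eqn{1 \le P \le N}.
#' @return object of class \code{ee_partition} with fields \code{n_rows},
#'   \code{n_workers}, \code{offsets} (length \eqn{P+1}, starting at 0).
#' @examples
#' partition_rows(10, 3)  # blocks of 4, 3, 3
#' @export
partition_rows <- function(N, P) {
  N <- as.integer(N); P <- as.integer(P)
  if (P < 1L || P > N) {
    abort_ee("number of workers must satisfy 1 <= P <= N", "ee_invalid_parameter")
  }
  base <- N %/% P
  extra <- N %% P
  sizes <- rep(base, P) + c(rep(1L, extra), rep(0L, P - extra))
  structure(
    list(n_rows = N, n_workers = P, offsets = c(0L, cumsum(sizes))),
    class = "ee_partition"
  )
}

#' Row indices owned by one worker
#'
#' @param part \code{ee_partition}.
#' @param i worker index in \code{1:P}.
#' @return integer vector of global row indices.
#' @export
block_rows <- function(part, i) {
  (part$offsets[i] + 1L):part$offsets[i + 1L]
}

#' Sigma-calibration order within a row block
#'
#' The same greedy nearest-neighbor chain used serially, restricted to the
#' block's own rows (each worker orders and warm-starts its root-finding
#' problems locally, without communication). With a single worker this is
#' exactly the serial order.
#'
#' @param D_block \eqn{M_i \times N} block of squared distances.
#' @param block_rows global row indices of the block.
#' @return permutation of \code{1:M_i} (local indices).
#' @export
block_sigma_order <- function(D_block, block_rows) {
  if (length(block_rows) == 0L) {
    abort_ee("block must be nonempty", "ee_invalid_input")
  }
  chain_order_from_dist(D_block[, block_rows, drop = FALSE])
}

# Stage A-C of the row-partitioned pipeline: per-worker distance blocks,
# locally ordered sigma calibration, attractive blocks symmetrized by
# exchanging transpose slices with peers, and normalization by rank-ordered
# global sums. Returns one state list per worker.
parallel_affinity <- function(Y, perplexity, part, times = NULL,
                              temporal_dialect = "squared") {
  N <- part$n_rows
  P <- part$n_workers
  rows_of <- lapply(seq_len(P), function(i) block_rows(part, i))

  # Part A: distance blocks and locally warm-started sigma calibration.
  D_blocks <- lapply(seq_len(P), function(i) cross_sq_dist(Y, rows_of[[i]]))
  sigma_blocks <- vector("list", P)
  for (i in seq_len(P)) {
    rows <- rows_of[[i]]
    ord <- block_sigma_order(D_blocks[[i]], rows)
    sig <- numeric(length(rows))
    init <- 1.0
    for (local in ord) {
      s <- tryCatch(
        calibrate_sigma(D_blocks[[i]][local, ], rows[local], perplexity,
                        init = init),
        ee_duplicate_degenerate = function(e) {
          warn_ee(sprintf("row %d duplicates every other point; sigma set to machine-tiny",
                          rows[local]), "ee_degenerate_row")
          .Machine$double.xmin
        }
      )
      sig[local] <- s
      if (s > .Machine$double.xmin) init <- s
    }
    sigma_blocks[[i]] <- sig
  }

  # Raw attractive blocks (sigma recycles along block rows).
  Wraw <- lapply(seq_len(P), function(i) {
    W <- attractive_kernel(D_blocks[[i]], sigma_blocks[[i]])
    W[cbind(seq_along(rows_of[[i]]), rows_of[[i]])] <- 0
    W
  })

  # Part B: symmetrization. Worker i obtains the transpose slice of each
  # peer's block (shared-memory read here; point-to-point exchange in a
  # distributed transport) and adds it to its own block.
  Wp_blocks <- lapply(seq_len(P), function(i) {
    What <- matrix(0, nrow = length(rows_of[[i]]), ncol = N)
    for (j in seq_len(P)) {
      What[, rows_of[[j]]] <- t(Wraw[[j]][, rows_of[[i]], drop = FALSE])
    }
    Wraw[[i]] + What
  })
  # Rank-ordered reduction of the normalizer.
  S_p <- sum(vapply(Wp_blocks, sum, numeric(1)))
  if (S_p <= 0) {
    abort_ee("all weights are zero; affinities are degenerate", "ee_degenerate_affinity")
  }
  Wp_blocks <- lapply(Wp_blocks, function(W) W / S_p)

  # Part C: repulsive blocks.
  S_n <- sum(vapply(D_blocks, sum, numeric(1)))
  if (S_n <= 0) {
    abort_ee("all samples are identical; repulsive weights are degenerate",
             "ee_degenerate_affinity")
  }
  Wn_blocks <- lapply(D_blocks, function(D) D / S_n)

  T_blocks <- NULL
  if (!is.null(times)) {
    if (length(times) != N) {
      abort_ee(sprintf("expected %d time stamps, got %d", N, length(times)),
               "ee_invalid_input")
    }
    T_blocks <- lapply(seq_len(P), function(i) {
      Tm <- outer(times[rows_of[[i]]], times, "-")
      Tm <- if (temporal_dialect == "squared") Tm * Tm else abs(Tm)
      Tm[cbind(seq_along(rows_of[[i]]), rows_of[[i]])] <- 0
      Tm
    })
    S_t <- sum(vapply(T_blocks, sum, numeric(1)))
    if (S_t <= 0) {
      warn_ee("all time stamps are identical; temporal term is zero and TSEE reduces to EE",
              "ee_constant_times")
      T_blocks <- NULL
    } else {
      T_blocks <- lapply(T_blocks, function(Tm) Tm / S_t)
    }
  }

  list(part = part, rows = rows_of, w_p = Wp_blocks, w_n = Wn_blocks,
       temporal = T_blocks,
       sigma = unlist(sigma_blocks, use.names = FALSE))
}

# Effective repulsive blocks for one worker (combined blocks cached in
# state$rep by parallel_fit).
block_repulsive <- function(state, i, params) {
  if (!is.null(state$rep)) {
    state$rep[[i]]
  } else if (!is.null(state$temporal) && params$beta > 0) {
    state$w_n[[i]] + params$beta * state$temporal[[i]]
  } else {
    state$w_n[[i]]
  }
}

#' Block-reduced elastic-embedding energy
#'
#' Evaluates the energy as a rank-ordered sum of per-worker partial sums,
#' each worker summing over its own row block against the full coordinate
#' matrix — the reduction used by every line-search trial of
#' [parallel_fit()].
#'
#' @param state worker state list produced inside [parallel_fit()] (also
#'   exposed via \code{elastica:::parallel_affinity} for testing).
#' @param X full \eqn{N \times d} coordinate matrix.
#' @param params \code{ee_params}.
#' @return scalar energy.
#' @export
parallel_energy <- function(state, X, params = ee_params()) {
  partials <- vapply(seq_along(state$rows), function(i) {
    Dx <- cross_sq_dist(X, state$rows[[i]])
    sum(state$w_p[[i]] * Dx) +
      params$lambda * sum(block_repulsive(state, i, params) * exp(-Dx))
  }, numeric(1))
  sum(partials)
}

# Per-block energy partial together with the block kernel (cached by the
# fit loop exactly as in the serial path).
block_energy_parts <- function(state, i, X, params) {
  Dx <- cross_sq_dist(X, state$rows[[i]])
  Ker <- exp(-Dx)
  e <- sum(state$w_p[[i]] * Dx) +
    params$lambda * sum(block_repulsive(state, i, params) * Ker)
  list(e = e, Ker = Ker)
}

# Per-worker gradient blocks; the caller all-gathers them in rank order.
parallel_gradient_blocks <- function(state, X, params, kernels = NULL) {
  lapply(seq_along(state$rows), function(i) {
    rows <- state$rows[[i]]
    Ker <- if (is.null(kernels)) exp(-cross_sq_dist(X, rows)) else kernels[[i]]
    Wk <- state$w_p[[i]] -
      params$lambda * block_repulsive(state, i, params) * Ker
    rs <- rowSums(Wk)
    4 * (rs * X[rows, , drop = FALSE] - Wk %*% X)
  })
}

#' Fit an elastic embedding with row-partitioned workers
#'
#' Runs the identical optimization as [ee_fit()] under a \code{P}-worker
#' contiguous row-block partition: every worker owns only its blocks of the
#' \eqn{N \times N} matrices (distances, attractive and repulsive weights,
#' kernel, iteration Laplacian, gradient rows); global scalars are reduced
#' from per-block partial sums in worker rank order; coordinates and search
#' directions are re-assembled by all-gather each iteration. Sigma
#' calibration is warm-started along a nearest-neighbor chain local to each
#' block, so bandwidths match the serial ones to solver precision. With
#' \code{workers = 1} the run is bitwise identical to the serial path; for
#' \code{workers > 1} the embeddings agree to round-off (relative Frobenius
#' error well below 1e-5).
#'
#' The regularized attractive Laplacian is assembled from the worker blocks
#' and factorized once as a collective operation (the in-process analogue of
#' a distributed factorization); the triangular factor is shared.
#'
#' @param Y numeric sample-by-feature matrix.
#' @param params \code{ee_params}.
#' @param workers number of row-block workers \code{P}.
#' @param X0 optional initial coordinates (defaults to the same seeded
#'   Gaussian initialization as [ee_fit()]).
#' @param times optional time stamps (time-series energy).
#' @return \code{ee_embedding}, as for [ee_fit()].
#' @export
parallel_fit <- function(Y, params = ee_params(), workers = 1L, X0 = NULL,
                         times = NULL) {
  Y <- as_data_matrix(Y)
  N <- nrow(Y)
  part <- partition_rows(N, workers)
  P <- part$n_workers
  state <- parallel_affinity(Y, params$perplexity, part, times = times)

  # Invariant: each worker holds M_i x N blocks only, never a full matrix.
  for (i in seq_len(P)) {
    stopifnot(nrow(state$w_p[[i]]) == length(state$rows[[i]]),
              ncol(state$w_p[[i]]) == N,
              nrow(state$w_n[[i]]) == length(state$rows[[i]]))
  }

  # Part D: assemble B = 4 L_P + mu I from the blocks and factorize once.
  trace4 <- sum(vapply(seq_len(P), function(i) {
    sum(4 * rowSums(state$w_p[[i]]))
  }, numeric(1)))
  mu <- params$mu
  if (identical(mu, "auto")) mu <- 1e-9 * trace4 / N
  if (!is.finite(mu) || mu <= 0) {
    abort_ee("regularizer mu must be positive", "ee_numerical_error")
  }
  B <- matrix(0, N, N)
  for (i in seq_len(P)) {
    rows <- state$rows[[i]]
    B[rows, ] <- -4 * state$w_p[[i]]
    B[cbind(rows, rows)] <- 4 * rowSums(state$w_p[[i]]) + mu
  }
  R <- tryCatch(
    chol(B),
    error = function(e) {
      abort_ee(paste0("Cholesky factorization of the preconditioner failed (",
                      conditionMessage(e), "); try a larger mu"),
               "ee_numerical_error")
    }
  )
  precond <- structure(list(matrix = B, chol = R, mu = mu),
                       class = "ee_preconditioner")
  rm(B)

  X <- if (is.null(X0)) initial_coords(N, params) else as_data_matrix(X0, "X0")
  if (nrow(X) != N || ncol(X) != params$dim) {
    abort_ee("X0 has the wrong shape", "ee_invalid_input")
  }

  # cache the combined repulsive blocks once
  if (!is.null(state$temporal) && params$beta > 0) {
    state$rep <- lapply(seq_len(P), function(i) {
      state$w_n[[i]] + params$beta * state$temporal[[i]]
    })
  }

  parts <- lapply(seq_len(P), function(i) block_energy_parts(state, i, X, params))
  E <- sum(vapply(parts, `[[`, numeric(1), "e"))
  kernels <- lapply(parts, `[[`, "Ker")
  energy_trace <- E
  step_trace <- numeric(0)
  converged <- FALSE
  reason <- "max_iter"
  alpha_prev <- NULL

  k <- 0L
  while (k < params$max_iter) {
    k <- k + 1L
    G_blocks <- parallel_gradient_blocks(state, X, params, kernels = kernels)
    G <- do.call(rbind, G_blocks)  # all-gather in rank order
    gnorm <- sqrt(sum(G * G))
    if (gnorm == 0) {
      converged <- TRUE; reason <- "zero_gradient"; k <- k - 1L; break
    }
    Pdir <- solve_direction(precond, G)
    gdot <- sum(G * Pdir)
    if (gdot >= 0) {
      converged <- TRUE; reason <- "step_failure"; k <- k - 1L; break
    }
    alpha_init <- if (is.null(alpha_prev)) 1 else min(1, 2 * alpha_prev)
    alpha <- alpha_init
    accepted <- FALSE
    E_new <- E
    for (trial in seq_len(61L)) {
      # Each trial re-reduces the block energies for the candidate step.
      Xt <- X + alpha * Pdir
      parts <- lapply(seq_len(P), function(i) {
        block_energy_parts(state, i, Xt, params)
      })
      E_new <- sum(vapply(parts, `[[`, numeric(1), "e"))
      if (is.finite(E_new) && E_new <= E + 1e-4 * alpha * gdot) {
        accepted <- TRUE
        break
      }
      alpha <- alpha * 0.8
    }
    if (!accepted) {
      converged <- TRUE; reason <- "step_failure"; k <- k - 1L; break
    }
    kernels <- lapply(parts, `[[`, "Ker")
    X <- X + alpha * Pdir
    E_prev <- E
    E <- E_new
    energy_trace <- c(energy_trace, E)
    step_trace <- c(step_trace, alpha)
    alpha_prev <- alpha
    if (params$verbose) {
      message(sprintf("iter %4d  energy %.10e  step %.3e  |grad| %.3e  [P=%d]",
                      k, E, alpha, gnorm, P))
    }
    if (abs(E - E_prev) <= params$tol * abs(E)) {
      converged <- TRUE; reason <- "energy_tol"; break
    }
  }

  structure(
    list(coords = X, energy_trace = energy_trace, step_trace = step_trace,
         n_iter = k, converged = converged, reason = reason,
         params = params, workers = P),
    class = "ee_embedding"
  )
}
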