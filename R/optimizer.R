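# Elastic-embedding energy minimization: spectral-direction quasi-Newton with
# a fixed factorized attractive-Laplacian preconditioner and Armijo
# backtracking.

#' Optimization parameters for elastic embedding
#'
#' @param lambda positive trade-off between the attractive and repulsive
#'   terms (default 10; larger favors global-structure preservation).
#' @param perplexity target perplexity for bandwidth calibration (default 20).
#' @param dim embedding dimension \eqn{d} (default 2).
#' @param beta non-negative weight of the temporal term (TSEE only,
#'   default 1).
#' @param mu positive diagonal regularizer of the attractive Laplacian, or
#'   \code{"auto"} for \code{1e-9 * trace(4 L_P) / N} (scale-free).
#' @param max_iter iteration cap (default 200).
#' @param tol relative energy-change convergence tolerance (default 1e-6).
#' @param seed integer seed for the Gaussian initialization.
#' @param init_scale standard deviation of the Gaussian initialization
#'   (default 1e-4).
#' @param verbose emit a per-iteration log line (iteration, energy, step,
#'   gradient norm).
#' @return object of class \code{ee_params}.
#' @export
ee_params <- function(lambda = 10, perplexity = 20, dim = 2L, beta = 1,
                      mu = "auto", max_iter = 200L, tol = 1e-6, seed = 0L,
                      init_scale = 1e-4, verbose = FALSE) {
  if (!is.numeric(lambda) || lambda <= 0) {
    abort_ee("`lambda` must be positive", "ee_invalid_parameter")
  }
  if (!is.numeric(dim) || dim < 1) {
    abort_ee("`dim` must be >= 1", "ee_invalid_parameter")
  }
  if (!is.numeric(tol) || tol <= 0) {
    abort_ee("`tol` must be positive", "ee_invalid_parameter")
  }
  if (!is.numeric(beta) || beta < 0) {
    abort_ee("`beta` must be non-negative", "ee_invalid_parameter")
  }
  if (!identical(mu, "auto") && (!is.numeric(mu) || length(mu) != 1L)) {
    abort_ee("`mu` must be a number or \"auto\"", "ee_invalid_parameter")
  }
  structure(
    list(lambda = lambda, perplexity = perplexity, dim = as.integer(dim),
         beta = beta, mu = mu, max_iter = as.integer(max_iter), tol = tol,
         seed = as.integer(seed), init_scale = init_scale, verbose = verbose),
    class = "ee_params"
  )
}

# Effective repulsive weight matrix: w_n, plus beta * temporal when present.
# fit() caches the combined matrix in model$rep so the sum is formed once.
repulsive_weights <- function(model, params) {
  if (!is.null(model$rep)) {
    model$rep
  } else if (!is.null(model$temporal) && params$beta > 0) {
    model$w_n + params$beta * model$temporal
  } else {
    model$w_n
  }
}

# Energy together with the kernel matrix exp(-|x_m - x_n|^2) it evaluates;
# the accepted line-search trial's kernel is exactly what the next gradient
# needs, so fit() caches it (identical values, one fewer N^2 pass per
# iteration).
energy_parts <- function(X, model, params) {
  Dx <- pairwise_sq_dist(X)
  Ker <- exp(-Dx)
  rep_w <- repulsive_weights(model, params)
  list(E = sum(model$w_p * Dx) + params$lambda * sum(rep_w * Ker), Ker = Ker)
}

#' Elastic-embedding energy
#'
#' \deqn{E(X) = \sum_{m,n} w^+_{nm} \|x_n - x_m\|^2
#'   + \lambda \sum_{m,n} (w^-_{nm} + \beta t_{nm})
#'     \exp(-\|x_n - x_m\|^2)}
#' with the temporal term present only for time-series models.
#'
#' @param X \eqn{N \times d} coordinate matrix.
#' @param model \code{ee_affinity} model.
#' @param params \code{ee_params}.
#' @return scalar energy.
#' @export
ee_energy <- function(X, model, params = ee_params()) {
  X <- as_data_matrix(X, "X")
  if (nrow(X) != model$n) {
    abort_ee("X and affinity model have different sample counts", "ee_invalid_input")
  }
  energy_parts(X, model, params)$E
}

#' Graph Laplacian
#'
#' \eqn{L = \mathrm{diag}(W \mathbf{1}) - W} for a symmetric non-negative
#' weight matrix with zero diagonal. Rows sum to zero; positive semidefinite.
#'
#' @param W symmetric matrix with zero diagonal.
#' @return symmetric Laplacian matrix.
#' @export
graph_laplacian <- function(W) {
  check_square_symmetric(W)
  L <- -W
  diag(L) <- diag(L) + rowSums(W)
  L
}

#' Energy gradient
#'
#' Returns \eqn{G = 4 L_k X} where \eqn{L_k} is the graph Laplacian of
#' \eqn{W_k = W_P - \lambda (W_N + \beta T) \circ \mathrm{Ker}} and
#' \eqn{\mathrm{Ker}_{mn} = \exp(-\|x_m - x_n\|^2)}. The leading factor 4
#' makes \eqn{G} the analytic differential of [ee_energy()] (the search
#' direction is unaffected by the constant and the line search absorbs its
#' scale).
#'
#' @inheritParams ee_energy
#' @param kernel optional precomputed kernel matrix
#'   \eqn{\exp(-\|x_m - x_n\|^2)} for this \code{X} (cached by the fit loop).
#' @return list with \code{G} (\eqn{N \times d}) and \code{work} (per-
#'   iteration matrices: \code{kernel}, \code{w_k}, row sums).
#' @export
ee_gradient <- function(X, model, params = ee_params(), kernel = NULL) {
  X <- as_data_matrix(X, "X")
  N <- nrow(X)
  if (N == 1L) {
    return(list(G = matrix(0, 1L, ncol(X)), work = NULL))
  }
  if (N != model$n) {
    abort_ee("X and affinity model have different sample counts", "ee_invalid_input")
  }
  Ker <- kernel %||% exp(-pairwise_sq_dist(X))
  Wk <- model$w_p - params$lambda * repulsive_weights(model, params) * Ker
  rs <- rowSums(Wk)
  G <- 4 * (rs * X - Wk %*% X)
  list(G = G, work = list(kernel = Ker, w_k = Wk, row_sums = rs))
}

#' Build the fixed spectral-direction preconditioner
#'
#' Assembles \eqn{B = 4 L_P + \mu I}, the regularized Laplacian of the
#' normalized attractive weights (the positive-definite part of the energy
#' Hessian, iteration-invariant), and factorizes it once by Cholesky
#' decomposition; the triangular factor is reused for every subsequent
#' direction solve.
#'
#' @param model \code{ee_affinity} model.
#' @param params \code{ee_params}; \code{params$mu} is the diagonal
#'   regularizer (number or \code{"auto"}).
#' @return object of class \code{ee_preconditioner} with fields
#'   \code{matrix}, \code{chol} (upper-triangular factor), \code{mu}.
#' @export
build_preconditioner <- function(model, params = ee_params()) {
  L4 <- 4 * graph_laplacian(model$w_p)
  mu <- params$mu
  if (identical(mu, "auto")) {
    mu <- 1e-9 * sum(diag(L4)) / model$n
  }
  if (!is.finite(mu) || mu <= 0) {
    abort_ee("regularizer mu must be positive: unregularized Laplacian is singular (constant vector in null space)",
             "ee_numerical_error")
  }
  B <- L4
  diag(B) <- diag(B) + mu
  R <- tryCatch(
    chol(B),
    error = function(e) {
      abort_ee(paste0("Cholesky factorization of the preconditioner failed (",
                      conditionMessage(e), "); try a larger mu"),
               "ee_numerical_error")
    }
  )
  structure(list(matrix = B, chol = R, mu = mu), class = "ee_preconditioner")
}

#' Solve for the spectral search direction
#'
#' Solves \eqn{B P = -G} using the cached triangular factor: two triangular
#' back-substitutions per call. Since \eqn{B} is positive definite the result
#' is a descent direction whenever \eqn{G \neq 0}.
#'
#' @param precond \code{ee_preconditioner}.
#' @param G \eqn{N \times d} gradient.
#' @return \eqn{N \times d} direction matrix.
#' @export
solve_direction <- function(precond, G) {
  if (!inherits(precond, "ee_preconditioner")) {
    abort_ee("`precond` must be an ee_preconditioner", "ee_invalid_input")
  }
  if (!is.matrix(G) || nrow(G) != nrow(precond$matrix)) {
    abort_ee("`G` has the wrong shape", "ee_invalid_input")
  }
  R <- precond$chol
  backsolve(R, backsolve(R, -G, transpose = TRUE))
}

#' Armijo backtracking line search
#'
#' Starting at \code{alpha_init}, multiplies the step by \eqn{\rho = 0.8}
#' until the Armijo condition
#' \eqn{E(X + \alpha P) \le E_0 + c\,\alpha \langle G, P \rangle_F} holds with
#' \eqn{c = 10^{-4}}. After 60 reductions without success a step-failure
#' signal is returned (the caller treats it as convergence).
#'
#' @param X current coordinates.
#' @param P descent direction (requires \eqn{\langle G,P\rangle_F < 0}).
#' @param E0 current energy.
#' @param G current gradient.
#' @param model,params as in [ee_energy()].
#' @param alpha_init initial trial step.
#' @return list with \code{alpha}, \code{energy}, \code{failed},
#'   \code{n_eval}.
#' @export
line_search <- function(X, P, E0, G, model, params, alpha_init = 1) {
  gdot <- sum(G * P)
  if (!is.finite(gdot) || gdot >= 0) {
    abort_ee("`P` is not a descent direction (<G,P> >= 0)", "ee_invalid_direction")
  }
  alpha <- alpha_init
  c1 <- 1e-4
  rho <- 0.8
  for (trial in seq_len(61L)) {
    E_new <- ee_energy(X + alpha * P, model, params)
    if (is.finite(E_new) && E_new <= E0 + c1 * alpha * gdot) {
      return(list(alpha = alpha, energy = E_new, failed = FALSE, n_eval = trial))
    }
    alpha <- alpha * rho
  }
  list(alpha = 0, energy = E0, failed = TRUE, n_eval = 61L)
}

# Gaussian initialization shared by the serial and row-partitioned paths.
initial_coords <- function(N, params) {
  with_seed(params$seed,
            matrix(stats::rnorm(N * params$dim, sd = params$init_scale),
                   nrow = N, ncol = params$dim))
}

#' Fit an elastic embedding
#'
#' Minimizes the (time-series) elastic-embedding energy by the spectral-
#' direction quasi-Newton scheme: the regularized attractive Laplacian is
#' factorized once; each iteration computes the gradient from the current
#' Gaussian kernel matrix, solves for the direction with the cached factor,
#' and takes an Armijo backtracking step (warm-started at
#' \eqn{\min(1, 2\alpha_{k-1})}). Iterations stop when the relative energy
#' change falls below \code{params$tol} or \code{params$max_iter} is reached.
#'
#' @param Y a numeric sample-by-feature matrix, or a prebuilt
#'   \code{ee_affinity} model.
#' @param params \code{ee_params}.
#' @param X0 optional \eqn{N \times d} initial coordinates; defaults to
#'   i.i.d. \eqn{N(0, \mathrm{init\_scale}^2)} drawn with \code{params$seed}.
#' @param times optional time stamps (ignored when \code{Y} is already a
#'   model); triggers the time-series energy.
#' @return object of class \code{ee_embedding}: \code{coords},
#'   \code{energy_trace} (length \code{n_iter + 1}, starting at the initial
#'   energy, non-increasing), \code{step_trace}, \code{n_iter},
#'   \code{converged}, \code{reason}.
#' @examples
#' Y <- matrix(rnorm(60), 30, 2)
#' emb <- ee_fit(Y, ee_params(perplexity = 5, max_iter = 20))
#' emb$n_iter
#' @export
ee_fit <- function(Y, params = ee_params(), X0 = NULL, times = NULL) {
  model <- if (inherits(Y, "ee_affinity")) {
    Y
  } else {
    ee_affinity(Y, perplexity = params$perplexity, times = times)
  }
  N <- model$n
  if (!(params$perplexity > 1 && params$perplexity <= N - 1) &&
      !inherits(Y, "ee_affinity")) {
    abort_ee("perplexity out of range for this N", "ee_invalid_parameter")
  }
  X <- if (is.null(X0)) initial_coords(N, params) else as_data_matrix(X0, "X0")
  if (nrow(X) != N || ncol(X) != params$dim) {
    abort_ee("X0 has the wrong shape", "ee_invalid_input")
  }

  model$rep <- repulsive_weights(model, params)
  precond <- build_preconditioner(model, params)
  ep <- energy_parts(X, model, params)
  E <- ep$E
  Ker <- ep$Ker
  energy_trace <- E
  step_trace <- numeric(0)
  converged <- FALSE
  reason <- "max_iter"
  alpha_prev <- NULL

  k <- 0L
  while (k < params$max_iter) {
    k <- k + 1L
    gr <- ee_gradient(X, model, params, kernel = Ker)
    G <- gr$G
    gnorm <- sqrt(sum(G * G))
    if (gnorm == 0) {
      converged <- TRUE
      reason <- "zero_gradient"
      k <- k - 1L
      break
    }
    P <- solve_direction(precond, G)
    gdot <- sum(G * P)
    if (gdot >= 0) {
      converged <- TRUE
      reason <- "step_failure"
      k <- k - 1L
      break
    }
    # Armijo backtracking, inlined so the accepted trial's kernel is kept
    # for the next gradient (numerically identical to line_search()).
    alpha <- if (is.null(alpha_prev)) 1 else min(1, 2 * alpha_prev)
    accepted <- FALSE
    for (trial in seq_len(61L)) {
      ep <- energy_parts(X + alpha * P, model, params)
      if (is.finite(ep$E) && ep$E <= E + 1e-4 * alpha * gdot) {
        accepted <- TRUE
        break
      }
      alpha <- alpha * 0.8
    }
    if (!accepted) {
      converged <- TRUE
      reason <- "step_failure"
      k <- k - 1L
      break
    }
    X <- X + alpha * P
    E_prev <- E
    E <- ep$E
    Ker <- ep$Ker
    energy_trace <- c(energy_trace, E)
    step_trace <- c(step_trace, alpha)
    alpha_prev <- alpha
    if (params$verbose) {
      message(sprintf("iter %4d  energy %.10e  step %.3e  |grad| %.3e",
                      k, E, alpha, gnorm))
    }
    if (abs(E - E_prev) <= params$tol * abs(E)) {
      converged <- TRUE
      reason <- "energy_tol"
      break
    }
  }

  structure(
    list(coords = X, energy_trace = energy_trace, step_trace = step_trace,
         n_iter = k, converged = converged, reason = reason,
         params = params),
    class = "ee_embedding"
  )
}

#' @export
print.ee_embedding <- function(x, ...) {
  cat(sprintf("Elastic embedding: %d x %d, %d iterations (%s), final energy %.8g\n",
              nrow(x$coords), ncol(x$coords), x$n_iter,
              if (x$converged) paste0("converged: ", x$reason) else "not converged",
              x$energy_trace[length(x$energy_trace)]))
  invisible(x)
}

#' Relative Frobenius error between two matrices
#'
#' \eqn{\|A - B\|_F / \|A\|_F}, the consistency metric between two
#' embeddings.
#'
#' @param A reference matrix (must be nonzero).
#' @param B comparison matrix of the same shape.
#' @return non-negative scalar.
#' @export
relative_error <- function(A, B) {
  if (!identical(dim(A), dim(B))) {
    abort_ee("A and B must have the same shape", "ee_invalid_input")
  }
  denom <- sqrt(sum(A * A))
  if (denom == 0) {
    abort_ee("relative error undefined: reference matrix is zero", "ee_undefined_error")
  }
  sqrt(sum((A - B)^2)) / denom
}
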