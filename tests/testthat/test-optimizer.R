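# Optimizer: energy, Laplacian, gradient, preconditioner, line search, fit.

test_that("ee_energy matches hand values and the double-loop oracle", {
  set.seed(2)
  Y <- matrix(rnorm(10), 5, 2)
  m <- ee_affinity(Y, perplexity = 3)
  p <- ee_params(lambda = 10, perplexity = 3)

  # coincident coordinates: attractive term 0, sum(w_n) = 1 => E = lambda
  X0 <- matrix(2.5, 5, 2)
  expect_equal(ee_energy(X0, m, p), 10, tolerance = 1e-12)

  # lambda -> 0 limit: energy is the nonnegative quadratic term only
  m0 <- toy_model(m$w_p, m$w_n)
  X <- matrix(rnorm(10), 5, 2)
  p_eps <- ee_params(lambda = 1e-300, perplexity = 3)
  expect_gte(ee_energy(X, m0, p_eps), 0)

  E <- ee_energy(X, m, p)
  expect_equal(E, oracle_energy(X, m$w_p, m$w_n, 10), tolerance = 1e-12)

  # TSEE path against the oracle
  tt <- runif(5)
  mt <- ee_affinity(Y, perplexity = 3, times = tt)
  pt <- ee_params(lambda = 10, perplexity = 3, beta = 0.6)
  expect_equal(ee_energy(X, mt, pt),
               oracle_energy(X, mt$w_p, mt$w_n, 10, mt$temporal, 0.6),
               tolerance = 1e-12)

  expect_error(ee_energy(matrix(0, 4, 2), m, p), class = "ee_invalid_input")
})

test_that("graph_laplacian is the standard rowsum-minus-weight form", {
  W <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(graph_laplacian(W), matrix(c(0.5, -0.5, -0.5, 0.5), 2))

  set.seed(6)
  W <- matrix(runif(36), 6, 6); W <- W + t(W); diag(W) <- 0
  L <- graph_laplacian(W)
  expect_lt(max(abs(L %*% rep(1, 6))), 1e-14)
  x <- rnorm(6)
  expect_equal(drop(t(x) %*% L %*% x), oracle_laplacian_quadform(W, x),
               tolerance = 1e-12)

  Wbad <- W; Wbad[1, 2] <- Wbad[1, 2] + 1
  expect_error(graph_laplacian(Wbad), class = "ee_invalid_input")
})

test_that("gradient matches central finite differences on EE and TSEE paths", {
  set.seed(31)
  for (case in 1:4) {
    N <- sample(5:9, 1)
    Y <- matrix(rnorm(N * 3), N, 3)
    tt <- if (case %% 2 == 0) runif(N) else NULL
    m <- ee_affinity(Y, perplexity = 3, times = tt)
    p <- ee_params(perplexity = 3, lambda = 10, beta = 0.8)
    X <- matrix(rnorm(N * 2, sd = 0.5), N, 2)
    G <- ee_gradient(X, m, p)$G
    h <- 1e-6
    Gfd <- matrix(0, N, 2)
    for (i in seq_len(N)) {
      for (j in 1:2) {
        Xp <- X; Xp[i, j] <- X[i, j] + h
        Xm <- X; Xm[i, j] <- X[i, j] - h
        Gfd[i, j] <- (ee_energy(Xp, m, p) - ee_energy(Xm, m, p)) / (2 * h)
      }
    }
    expect_lt(max(abs(G - Gfd)) / max(abs(Gfd)), 1e-5)
  }
})

test_that("gradient vanishes at coincident coordinates and for a single point", {
  set.seed(12)
  Y <- matrix(rnorm(12), 6, 2)
  m <- ee_affinity(Y, perplexity = 3)
  X <- matrix(rep(c(1.2, -0.4), each = 6), 6, 2)
  G <- ee_gradient(X, m, ee_params(perplexity = 3))$G
  expect_lt(max(abs(G)), 1e-14)

  G1 <- ee_gradient(matrix(c(1, 2), 1, 2), toy_model(matrix(0, 1, 1), matrix(0, 1, 1)),
                    ee_params())$G
  expect_identical(G1, matrix(0, 1, 2))

  # translation invariance: gradient rows sum to ~0
  Xr <- matrix(rnorm(12), 6, 2)
  Gr <- ee_gradient(Xr, m, ee_params(perplexity = 3))$G
  expect_lt(max(abs(colSums(Gr))), 1e-10)
  shift <- matrix(rep(c(5, -3), each = 6), 6, 2)
  expect_equal(ee_energy(Xr, m, ee_params(perplexity = 3)),
               ee_energy(Xr + shift, m, ee_params(perplexity = 3)),
               tolerance = 1e-9)
})

test_that("preconditioner is the regularized attractive Laplacian, factorized once", {
  mu <- 0.25
  m2 <- toy_model(matrix(c(0, .5, .5, 0), 2), matrix(c(0, .5, .5, 0), 2))
  pc <- build_preconditioner(m2, ee_params(mu = mu))
  expect_equal(pc$matrix, matrix(c(2 + mu, -2, -2, 2 + mu), 2))

  set.seed(15)
  Y <- matrix(rnorm(16), 8, 2)
  m <- ee_affinity(Y, perplexity = 4)
  pc <- build_preconditioner(m, ee_params(perplexity = 4))
  ev <- eigen(pc$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), pc$mu - 1e-12)

  expect_error(build_preconditioner(m, ee_params(perplexity = 4, mu = 0)),
               class = "ee_numerical_error")
})

test_that("solve_direction solves B P = -G to backward-stable accuracy", {
  set.seed(16)
  Y <- matrix(rnorm(20), 10, 2)
  m <- ee_affinity(Y, perplexity = 4)
  pc <- build_preconditioner(m, ee_params(perplexity = 4, mu = 1e-3))

  expect_identical(solve_direction(pc, matrix(0, 10, 2)), matrix(0, 10, 2))

  G <- matrix(rnorm(20), 10, 2)
  P <- solve_direction(pc, G)
  resid <- pc$matrix %*% P + G
  expect_lt(sqrt(sum(resid^2)), 1e-8 * sqrt(sum(G^2)))
  expect_equal(P, solve(pc$matrix, -G), tolerance = 1e-8)
  expect_lt(sum(G * P), 0)  # descent direction

  # identity-dominant B: P ~ -G / mu
  mI <- toy_model(matrix(c(0, 1e-14, 1e-14, 0), 2), matrix(c(0, .5, .5, 0), 2))
  pcI <- build_preconditioner(mI, ee_params(mu = 1))
  GI <- matrix(rnorm(4), 2, 2)
  expect_equal(solve_direction(pcI, GI), -GI, tolerance = 1e-10)
})

test_that("line_search implements Armijo backtracking", {
  set.seed(17)
  Y <- matrix(rnorm(16), 8, 2)
  m <- ee_affinity(Y, perplexity = 4)

  # quadratic-only energy (lambda ~ 0) with its own Hessian as B:
  # the full Newton step is accepted at alpha = 1
  p0 <- ee_params(perplexity = 4, lambda = 1e-300, mu = 1e-12)
  X <- matrix(rnorm(16), 8, 2)
  E0 <- ee_energy(X, m, p0)
  G <- ee_gradient(X, m, p0)$G
  pc <- build_preconditioner(m, p0)
  P <- solve_direction(pc, G)
  ls <- line_search(X, P, E0, G, m, p0, alpha_init = 1)
  expect_false(ls$failed)
  expect_identical(ls$alpha, 1)

  # steepest descent with a tiny step always decreases the energy
  p <- ee_params(perplexity = 4)
  E0 <- ee_energy(X, m, p)
  G <- ee_gradient(X, m, p)$G
  ls <- line_search(X, -G, E0, G, m, p, alpha_init = 1e-6)
  expect_false(ls$failed)
  expect_identical(ls$alpha, 1e-6)
  expect_lt(ls$energy, E0)

  # sign-flipped gradient is not a descent direction
  expect_error(line_search(X, G, E0, G, m, p), class = "ee_invalid_direction")
})

test_that("two-point fit converges to squared separation ln(lambda)", {
  for (lam in c(exp(1), 10)) {
    m2 <- toy_model(matrix(c(0, .5, .5, 0), 2), matrix(c(0, .5, .5, 0), 2))
    p <- ee_params(lambda = lam, max_iter = 500, tol = 1e-12, seed = 3)
    emb <- ee_fit(m2, p)
    d2 <- sum((emb$coords[1, ] - emb$coords[2, ])^2)
    expect_lt(abs(d2 - log(lam)), 1e-4)
  }
})

test_that("fit descends monotonically, is deterministic, and separates clusters", {
  ds <- make_clusters(150, 3, 10, separation = 12, seed = 41)
  p <- ee_params(perplexity = 15, max_iter = 80, seed = 7)
  emb <- ee_fit(ds$data, p)
  expect_true(all(diff(emb$energy_trace) <= 1e-12))
  expect_gte(knn1_agreement(emb$coords, ds$labels), 0.95)

  emb2 <- ee_fit(ds$data, p)
  expect_identical(emb$coords, emb2$coords)
  expect_identical(emb$energy_trace, emb2$energy_trace)
})

test_that("TSEE with beta = 0 reproduces the EE trace bitwise", {
  set.seed(19)
  Y <- matrix(rnorm(50), 25, 2)
  tt <- runif(25)
  p <- ee_params(perplexity = 6, beta = 0, max_iter = 40, seed = 2)
  e_ee <- ee_fit(Y, p)
  e_ts <- ee_fit(Y, p, times = tt)
  expect_identical(e_ee$energy_trace, e_ts$energy_trace)
  expect_identical(e_ee$coords, e_ts$coords)
})

test_that("relative_error is the Frobenius ratio", {
  A <- matrix(c(3, 0, 0, 4), 2)
  expect_identical(relative_error(A, A), 0)
  expect_identical(relative_error(A, 0 * A), 1)
  B <- A; B[2, 2] <- 5
  expect_equal(relative_error(A, B), 0.2)
  expect_error(relative_error(A, matrix(0, 3, 2)), class = "ee_invalid_input")
  expect_error(relative_error(0 * A, A), class = "ee_undefined_error")
})
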