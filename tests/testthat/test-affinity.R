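# Affinity stage: distances, bandwidth calibration, weight normalization,
# temporal dissimilarities.

test_that("pairwise_sq_dist matches hand values and the double-loop oracle", {
  expect_equal(pairwise_sq_dist(matrix(c(0, 3), ncol = 1)),
               matrix(c(0, 9, 9, 0), 2))

  Y <- rbind(c(1, 2, 3), c(1, 2, 3), c(0, 0, 1))
  D <- pairwise_sq_dist(Y)
  expect_identical(D[1, 2], 0)           # identical rows
  expect_identical(diag(D), rep(0, 3))

  Y <- fixture_gaussian(5, 3, seed = 11)
  D <- pairwise_sq_dist(Y)
  expect_lt(max(abs(D - oracle_sq_dist(Y))), 1e-12)
  expect_identical(D, t(D))
  expect_true(all(D >= 0))

  expect_error(pairwise_sq_dist(matrix(c(1, NA), 1)), class = "ee_invalid_input")
})

test_that("calibrate_sigma hits the target perplexity and handles edge cases", {
  # 4 equidistant neighbors, target 4: perplexity is 4 for every sigma.
  D_row <- c(0, rep(2.5, 4))
  expect_identical(calibrate_sigma(D_row, 1L, 4, init = 1.7), 1.7)

  # Frozen oracle value for off-distances (1, 4, 9), target 2.
  off <- c(1, 4, 9)
  s_oracle <- oracle_sigma(off, 2.0)
  s <- calibrate_sigma(c(0, off), 1L, 2.0, init = 1.0)
  expect_equal(s, s_oracle, tolerance = 1e-8)
  expect_lt(abs(oracle_perplexity(off, s) - 2.0), 1e-6 * 2.0)

  # Perplexity out of range (must be <= N - 1).
  expect_error(calibrate_sigma(c(0, 1, 2, 3), 1L, 4),
               class = "ee_invalid_parameter")
  expect_error(calibrate_sigma(c(0, 1, 2, 3), 1L, 1),
               class = "ee_invalid_parameter")

  # Duplicate-degenerate row.
  expect_error(calibrate_sigma(c(0, 0, 0), 1L, 1.5),
               class = "ee_duplicate_degenerate")
})

test_that("calibrate_all_sigmas is order-invariant and matches per-row solves", {
  Y <- fixture_gaussian(12, 4, seed = 3)
  D <- pairwise_sq_dist(Y)
  K <- 5
  s_chain <- calibrate_all_sigmas(D, K)
  set.seed(9)
  s_perm <- calibrate_all_sigmas(D, K, order = sample(12))
  expect_lt(max(abs(s_chain - s_perm) / s_chain), 1e-6)

  for (n in c(1, 7, 12)) {
    achieved <- oracle_perplexity(D[n, -n], s_chain[n])
    expect_lt(abs(achieved - K) / K, 1e-6)
    expect_equal(s_chain[n], calibrate_sigma(D[n, ], n, K), tolerance = 1e-9)
  }

  expect_error(calibrate_all_sigmas(D, K, order = c(1:11, 11)),
               class = "ee_invalid_parameter")
})

test_that("duplicate rows get machine-tiny sigma with a warning", {
  Y <- rbind(c(0, 0), c(0, 0), c(0, 0))
  D <- pairwise_sq_dist(Y)
  # all rows duplicate each other; every row takes the degenerate path
  warns <- capture_warnings(s <- calibrate_all_sigmas(D, 1.5))
  expect_length(warns, 3)
  expect_true(all(s == .Machine$double.xmin))
  # build_attractive then yields the uniform conditional over duplicates
  W <- build_attractive(D, s)
  expect_identical(W[1, 2], 1)
  expect_identical(diag(W), rep(0, 3))
})

test_that("build_attractive matches the scalar formula", {
  sig <- c(0.7, 1.3, 2.1, 0.4)
  Y <- fixture_gaussian(4, 2, seed = 5)
  D <- pairwise_sq_dist(Y)
  W <- build_attractive(D, sig)
  for (n in 1:4) {
    for (m in 1:4) {
      expected <- if (n == m) 0 else exp(-D[n, m] / (2 * sig[n]^2))
      expect_equal(W[n, m], expected)
    }
  }
  # analytically forced entries
  D2 <- matrix(c(0, 2 * sig[1]^2, 2 * sig[1]^2, 0), 2)
  expect_equal(build_attractive(D2, sig[1:2])[1, 2], exp(-1))
  expect_error(build_attractive(D, c(1, -1, 1, 1)), class = "ee_invalid_parameter")
})

test_that("symmetrize_normalize and normalize_repulsive produce unit-sum symmetric weights", {
  expect_equal(symmetrize_normalize(matrix(c(0, 3, 1, 0), 2)),
               matrix(c(0, 0.5, 0.5, 0), 2))

  set.seed(4)
  W <- matrix(runif(25), 5, 5); diag(W) <- 0
  S <- symmetrize_normalize(W)
  expect_lt(abs(sum(S) - 1), 1e-14)
  expect_identical(S, t(S))
  expect_error(symmetrize_normalize(matrix(0, 3, 3)),
               class = "ee_degenerate_affinity")
  expect_error(symmetrize_normalize(diag(2)), class = "ee_invalid_input")

  # two points: off-diagonals 0.5 each
  D2 <- pairwise_sq_dist(matrix(c(0, 7), ncol = 1))
  expect_equal(normalize_repulsive(D2), matrix(c(0, .5, .5, 0), 2))
  # collinear points at 0, 1, 2: distances proportional to (1, 4, 1) pairs
  D3 <- pairwise_sq_dist(matrix(c(0, 1, 2), ncol = 1))
  WN <- normalize_repulsive(D3)
  expect_equal(WN[1, 2], 1 / 12)
  expect_equal(WN[1, 3], 4 / 12)
  expect_equal(sum(WN), 1)
  expect_error(normalize_repulsive(matrix(0, 3, 3)),
               class = "ee_degenerate_affinity")
})

test_that("build_temporal normalizes squared time differences", {
  expect_equal(build_temporal(c(0, 1)), matrix(c(0, .5, .5, 0), 2))
  expect_warning(Tm <- build_temporal(c(2, 2, 2)), class = "ee_constant_times")
  expect_identical(Tm, matrix(0, 3, 3))

  tt <- c(0, 0.5, 1)
  Tm <- build_temporal(tt)
  raw <- outer(tt, tt, "-")^2
  expect_equal(Tm, raw / sum(raw))
  expect_equal(sum(Tm), 1)

  Ta <- build_temporal(tt, dialect = "absolute")
  rawa <- abs(outer(tt, tt, "-"))
  expect_equal(Ta, rawa / sum(rawa))

  expect_error(build_temporal(c(0, 1), n_expected = 3), class = "ee_invalid_input")
})

test_that("affinity invariants hold on random inputs (property)", {
  set.seed(100)
  for (case in 1:5) {
    N <- sample(6:15, 1)
    Y <- matrix(rnorm(N * 3), N, 3)
    K <- runif(1, 2, N - 2)
    m <- ee_affinity(Y, perplexity = K)
    expect_lt(abs(sum(m$w_p) - 1), 1e-12)
    expect_lt(abs(sum(m$w_n) - 1), 1e-12)
    expect_identical(m$w_p, t(m$w_p))
    expect_identical(m$w_n, t(m$w_n))
    expect_identical(diag(m$w_p), rep(0, N))
    expect_identical(diag(m$w_n), rep(0, N))
    D <- pairwise_sq_dist(Y)
    perp <- vapply(seq_len(N), function(n) oracle_perplexity(D[n, -n], m$sigma[n]),
                   numeric(1))
    expect_true(all(abs(perp - K) <= 1e-6 * K))
  }
})

test_that("rescaling the data rescales distances and sigmas but not the conditionals", {
  Y <- fixture_gaussian(10, 3, seed = 8)
  c0 <- 3.7
  D1 <- pairwise_sq_dist(Y)
  D2 <- pairwise_sq_dist(c0 * Y)
  expect_equal(D2, c0^2 * D1, tolerance = 1e-12)
  s1 <- calibrate_all_sigmas(D1, 4)
  s2 <- calibrate_all_sigmas(D2, 4)
  expect_equal(s2, c0 * s1, tolerance = 1e-6)
  # conditional distributions coincide after recalibration
  p1 <- exp(-D1[1, -1] / (2 * s1[1]^2)); p1 <- p1 / sum(p1)
  p2 <- exp(-D2[1, -1] / (2 * s2[1]^2)); p2 <- p2 / sum(p2)
  expect_equal(p1, p2, tolerance = 1e-6)
})
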