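# Desk-scale synthetic datasets: a branching tree progression, a Gaussian
# cluster mixture, and staged time-series data. All generators are pure
# functions of their arguments and the seed (the caller's RNG state is
# preserved).

# Uniform random unit vector in n_features dimensions.
random_unit_direction <- function(n_features) {
  v <- stats::rnorm(n_features)
  v / sqrt(sum(v * v))
}

#' Branching tree dataset
#'
#' Emulates a tree-structured developmental progression: branch 1 is a
#' straight segment from the origin along a random unit direction; each
#' subsequent branch starts at a uniformly chosen point on a uniformly chosen
#' existing branch and extends in a fresh random direction. Points are placed
#' at uniform arc positions along their branch and perturbed by isotropic
#' Gaussian noise. At the default call
#' \code{make_tree(10, 144, 60, 0.1, seed)} this yields a 1,440 x 60 matrix
#' with 10 branch labels, the shape of the branching benchmark used to test
#' embedding consistency.
#'
#' @param n_branches number of branches (>= 1).
#' @param per_branch points per branch.
#' @param n_features ambient dimension.
#' @param noise_sd isotropic noise standard deviation (0 places every point
#'   exactly on its segment).
#' @param seed integer seed.
#' @param branch_length segment length (default 5, comfortably above the
#'   default noise so the topology is recoverable).
#' @return list of class \code{ee_dataset}: \code{data} (matrix),
#'   \code{labels} (integer branch ids), \code{times} (NULL).
#' @export
make_tree <- function(n_branches, per_branch, n_features, noise_sd = 0.1,
                      seed = 0L, branch_length = 5) {
  if (n_branches < 1L) abort_ee("n_branches must be >= 1", "ee_invalid_parameter")
  with_seed(seed, {
    starts <- vector("list", n_branches)
    dirs <- vector("list", n_branches)
    starts[[1L]] <- rep(0, n_features)
    dirs[[1L]] <- random_unit_direction(n_features)
    anchors <- matrix(0, nrow = n_branches * per_branch, ncol = n_features)
    labels <- rep(seq_len(n_branches), each = per_branch)
    pos <- seq_len(per_branch) / per_branch
    for (b in seq_len(n_branches)) {
      if (b > 1L) {
        parent <- sample.int(b - 1L, 1L)
        at <- stats::runif(1L)
        starts[[b]] <- starts[[parent]] + at * branch_length * dirs[[parent]]
        dirs[[b]] <- random_unit_direction(n_features)
      }
      idx <- which(labels == b)
      anchors[idx, ] <- rep(starts[[b]], each = per_branch) +
        (pos * branch_length) %o% dirs[[b]]
    }
    noise <- if (noise_sd > 0) {
      matrix(stats::rnorm(length(anchors), sd = noise_sd),
             nrow = nrow(anchors))
    } else {
      0
    }
    structure(list(data = anchors + noise, labels = labels, times = NULL),
              class = "ee_dataset")
  })
}

#' Gaussian cluster mixture dataset
#'
#' Near-equal-size isotropic unit-variance Gaussian blobs whose centers are
#' at pairwise distance at least \code{separation}. A stand-in for a
#' bifurcating cell population: \code{make_clusters(4423, 4, 50, 10, seed)}
#' matches the scale of the hematopoietic benchmark.
#'
#' @param n_samples total number of points.
#' @param n_clusters number of blobs (>= 1).
#' @param n_features ambient dimension.
#' @param separation minimum pairwise center distance.
#' @param seed integer seed.
#' @return \code{ee_dataset} with integer cluster labels.
#' @export
make_clusters <- function(n_samples, n_clusters, n_features, separation = 10,
                          seed = 0L) {
  if (n_clusters < 1L) abort_ee("n_clusters must be >= 1", "ee_invalid_parameter")
  with_seed(seed, {
    centers <- matrix(0, n_clusters, n_features)
    k <- 1L
    tries <- 0L
    while (k <= n_clusters && tries < 10000L) {
      cand <- stats::rnorm(n_features, sd = max(separation, 1))
      ok <- k == 1L ||
        all(sqrt(rowSums((centers[seq_len(k - 1L), , drop = FALSE] -
                            rep(cand, each = k - 1L))^2)) >= separation)
      if (ok) {
        centers[k, ] <- cand
        k <- k + 1L
      }
      tries <- tries + 1L
    }
    if (k <= n_clusters) {
      abort_ee("could not place cluster centers at the requested separation",
               "ee_invalid_parameter")
    }
    base <- n_samples %/% n_clusters
    extra <- n_samples %% n_clusters
    sizes <- rep(base, n_clusters) + c(rep(1L, extra), rep(0L, n_clusters - extra))
    labels <- rep(seq_len(n_clusters), times = sizes)
    X <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
    structure(list(data = X, labels = labels, times = NULL),
              class = "ee_dataset")
  })
}

#' Staged time-series dataset
#'
#' A drifting Gaussian population along a smoothly curving path: the stage
#' centers follow a unit-step random walk whose direction turns slowly, so
#' consecutive-stage centroids are closer than skip-stage centroids. Stage
#' \eqn{s} receives time stamp \eqn{s \cdot dt}; with
#' \code{make_timeseries(39, per_stage, n_features, 0.5, seed)} the stamps
#' reproduce a half-unit-interval design with 39 time points.
#'
#' @param n_stages number of stages (>= 2).
#' @param per_stage points per stage.
#' @param n_features ambient dimension.
#' @param dt time spacing between consecutive stages (default 0.5).
#' @param seed integer seed.
#' @param noise_sd within-stage isotropic spread (default 0.3, well below
#'   the unit inter-stage step).
#' @return \code{ee_dataset} with stage labels and populated \code{times}.
#' @export
make_timeseries <- function(n_stages, per_stage, n_features, dt = 0.5,
                            seed = 0L, noise_sd = 0.3) {
  if (n_stages < 2L) abort_ee("n_stages must be >= 2", "ee_invalid_parameter")
  with_seed(seed, {
    centers <- matrix(0, n_stages, n_features)
    dir <- random_unit_direction(n_features)
    for (s in 2:n_stages) {
      # Slowly turning direction keeps the path curved but locally straight.
      dir <- dir + 0.3 * stats::rnorm(n_features) / sqrt(n_features)
      dir <- dir / sqrt(sum(dir * dir))
      centers[s, ] <- centers[s - 1L, ] + dir
    }
    labels <- rep(seq_len(n_stages), each = per_stage)
    X <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_stages * per_stage * n_features), ncol = n_features,
             nrow = n_stages * per_stage) * noise_sd
    times <- (labels - 1L) * dt
    structure(list(data = X, labels = labels, times = times),
              class = "ee_dataset")
  })
}

#' @export
print.ee_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d x %d, %d groups%s\n",
              nrow(x$data), ncol(x$data), length(unique(x$labels)),
              if (is.null(x$times)) "" else
                sprintf(", %d time points", length(unique(x$times)))))
  invisible(x)
}
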