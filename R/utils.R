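# Internal helpers: condition classes, seeded evaluation, input checks.

# All package errors carry class c(<specific>, "ee_error") so callers can
# condition on either the precise failure or any elastica failure.
abort_ee <- function(message, class) {
  cond <- structure(
    class = c(class, "ee_error", "error", "condition"),
    list(message = message, call = sys.call(-1L))
  )
  stop(cond)
}

warn_ee <- function(message, class) {
  cond <- structure(
    class = c(class, "ee_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1L))
  )
  warning(cond)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators stay pure functions of (arguments, seed).
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Coerce to a validated dense numeric sample x feature matrix.
as_data_matrix <- function(Y, arg = "Y") {
  if (is.data.frame(Y)) Y <- as.matrix(Y)
  if (!is.matrix(Y) || !is.numeric(Y)) {
    abort_ee(sprintf("`%s` must be a numeric matrix", arg), "ee_invalid_input")
  }
  if (!all(is.finite(Y))) {
    abort_ee(sprintf("`%s` contains non-finite values", arg), "ee_invalid_input")
  }
  Y
}

check_square_symmetric <- function(W, arg = "W", tol = 1e-12) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    abort_ee(sprintf("`%s` must be a square matrix", arg), "ee_invalid_input")
  }
  scale <- max(abs(W), 1)
  if (max(abs(W - t(W))) > tol * scale) {
    abort_ee(sprintf("`%s` must be symmetric", arg), "ee_invalid_input")
  }
  invisible(W)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
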