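#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so that seeded generators behave as pure functions of
#' their inputs without disturbing the caller's stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# log(exp(a) + exp(b)) without overflow; a, b may be -Inf
log_add <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

# row-wise softmax, numerically stable
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# one-hot matrix for 0-based labels
onehot_rows <- function(y, n_classes) {
  out <- matrix(0, nrow = length(y), ncol = n_classes)
  out[cbind(seq_along(y), y + 1L)] <- 1
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# permutation / draw that never falls into sample()'s scalar trap
shuffle <- function(x) x[sample.int(length(x))]
draw <- function(x, n) x[sample.int(length(x), n)]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
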