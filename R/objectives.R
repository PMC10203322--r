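# Probabilities are clamped to this floor inside logarithms so losses stay
# finite; at double precision it does not measurably change any loss value.
PROB_FLOOR <- 1e-12

#' Mutual-learning mixing weights
#'
#' `alpha` weights the KL term in the private model's objective, `beta` the
#' KL term in the proxy's. Both lie strictly inside (0, 1); the boundary
#' values 0 and 1 are accepted only with `diagnostic = TRUE`, for reduction
#' checks against plain cross-entropy or pure distillation.
#'
#' @param alpha,beta Reals in (0, 1).
#' @param diagnostic Allow boundary values.
#' @return An object of class `pfl_mutual_weights`.
#' @export
mutual_weights <- function(alpha = 0.5, beta = 0.5, diagnostic = FALSE) {
  lo <- if (diagnostic) 0 else .Machine$double.eps
  hi <- if (diagnostic) 1 else 1 - .Machine$double.eps
  if (alpha < lo || alpha > hi)
    stopf("alpha must lie in (0, 1), got %s", format(alpha))
  if (beta < lo || beta > hi)
    stopf("beta must lie in (0, 1), got %s", format(beta))
  structure(list(alpha = alpha, beta = beta), class = "pfl_mutual_weights")
}

#' Per-example cross-entropy loss
#'
#' @param probs Probability matrix `[B, C]` (rows on the simplex).
#' @param y Integer labels in `[0, C)`.
#' @return Nonnegative per-example loss vector, `-log probs[i, y_i]` with
#'   the probability floor applied inside the log.
#' @export
ce_loss <- function(probs, y) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  y <- as.integer(y)
  if (length(y) != nrow(probs))
    stopf("labels (%d) do not match probability rows (%d)", length(y),
          nrow(probs))
  if (any(y < 0L) || any(y >= ncol(probs)))
    stopf("labels must lie in [0, %d)", ncol(probs))
  -log(pmax(probs[cbind(seq_len(nrow(probs)), y + 1L)], PROB_FLOOR))
}

#' Per-example KL divergence between probability rows
#'
#' @param p_rows,q_rows Probability matrices of identical shape.
#' @return Nonnegative per-example vector of `KL(p_i || q_i)`.
#' @export
kl_loss <- function(p_rows, q_rows) {
  if (is.null(dim(p_rows))) p_rows <- matrix(p_rows, nrow = 1L)
  if (is.null(dim(q_rows))) q_rows <- matrix(q_rows, nrow = 1L)
  if (!all(dim(p_rows) == dim(q_rows)))
    stopf("shape mismatch: %s vs %s", paste(dim(p_rows), collapse = "x"),
          paste(dim(q_rows), collapse = "x"))
  ell <- log(pmax(p_rows, PROB_FLOOR)) - log(pmax(q_rows, PROB_FLOOR))
  rowSums(p_rows * ell)
}

#' Deep-mutual-learning objectives
#'
#' The private objective is `(1 - alpha) * mean CE(private) +
#' alpha * mean KL(private || proxy)`; the proxy objective mirrors it with
#' `beta` and the KL direction reversed (`KL(proxy || private)`). The peer
#' model's predictions are constants: no gradient flows into the peer.
#'
#' @param private,proxy `pfl_classifier` objects sharing input/output spaces.
#' @param batch A `pfl_batch`.
#' @param w A [mutual_weights()] object.
#' @return Scalar objective value.
#' @export
private_objective <- function(private, proxy, batch, w) {
  mixed_objective(private, proxy, batch, w$alpha)
}

#' @rdname private_objective
#' @export
proxy_objective <- function(proxy, private, batch, w) {
  mixed_objective(proxy, private, batch, w$beta)
}

mixed_objective <- function(model, peer, batch, weight) {
  if (weight < 0 || weight > 1) stopf("mixing weight must lie in [0, 1]")
  p <- forward_probs(model, batch$x)
  val <- (1 - weight) * mean(ce_loss(p, batch$y))
  if (weight > 0) {
    q <- forward_probs(peer, batch$x)
    val <- val + weight * mean(kl_loss(p, q))
  }
  val
}

#' Per-example mixed (mutual-learning) gradients
#'
#' Row `i` is `(1 - weight) * grad CE[f(x_i) || y_i] +
#' weight * grad KL[f(x_i) || h(x_i)]`, taken with respect to the first
#' model's parameters only; the peer's outputs are detached constants.
#' This is the per-example gradient that DP-SGD clips.
#'
#' @param model Model whose parameters the gradient is taken w.r.t.
#' @param peer Peer model providing the distillation targets; may be `NULL`
#'   when `weight = 0`.
#' @param batch A `pfl_batch`.
#' @param weight KL mixing weight in `[0, 1]`.
#' @return Matrix `[B, n_params]`.
#' @export
mixed_per_example_grads <- function(model, peer, batch, weight) {
  if (weight < 0 || weight > 1) stopf("mixing weight must lie in [0, 1]")
  if (weight == 0) return(per_example_grads(model, batch, loss_ce()))
  if (is.null(peer)) stopf("peer model required when weight > 0")
  q <- forward_probs(peer, batch$x)
  per_example_grads(model, batch, loss_mixed(weight, q))
}
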