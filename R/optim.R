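#' Apply an optimizer update to a flat parameter vector
#'
#' Implements plain SGD (`params - lr * grad`) and Adam with bias
#' correction (beta1 = 0.9, beta2 = 0.999, eps = 1e-8). Decoupled-style L2
#' weight decay is folded into the gradient before the moment updates, as
#' in the common DP-Adam usage where the privatized mean gradient is fed to
#' an ordinary Adam step.
#'
#' @param params Flat numeric parameter vector.
#' @param grad Gradient vector of the same length.
#' @param state Optimizer state from a previous call, or `NULL` to start
#'   fresh (Adam moments at zero, step count 0).
#' @param rule `"sgd"` or `"adam"`.
#' @param lr Learning rate.
#' @param weight_decay L2 penalty coefficient added to the gradient.
#' @return `list(params = updated vector, state = advanced state)`.
#' @export
apply_update <- function(params, grad, state = NULL,
                         rule = c("sgd", "adam"), lr, weight_decay = 0) {
  rule <- match.arg(rule)
  if (length(grad) != length(params))
    stopf("gradient length %d does not match parameter length %d",
          length(grad), length(params))
  if (weight_decay != 0) grad <- grad + weight_decay * params
  if (rule == "sgd") {
    return(list(params = params - lr * grad, state = state %||% list(t = 0L)))
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  if (is.null(state)) {
    state <- list(t = 0L, m = numeric(length(params)),
                  v = numeric(length(params)))
  }
  t <- state$t + 1L
  m <- b1 * state$m + (1 - b1) * grad
  v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(params = params - lr * mhat / (sqrt(vhat) + eps),
       state = list(t = t, m = m, v = v))
}

# bundled optimizer convenience used by the protocol drivers
make_optimizer <- function(rule = "adam", lr = 0.001, weight_decay = 0) {
  list(rule = rule, lr = lr, weight_decay = weight_decay, state = NULL)
}

opt_step <- function(model, grad, opt) {
  upd <- apply_update(model$params, grad, opt$state, opt$rule, opt$lr,
                      opt$weight_decay)
  opt$state <- upd$state
  list(model = set_params(model, upd$params), opt = opt)
}
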