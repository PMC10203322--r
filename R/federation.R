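# Communication topology and PushSum gossip. Communication is simulated
# in-process against the same column-stochastic adjacency contract a
# message-passing deployment would use: the only quantities that ever move
# between clients are proxy parameter vectors and PushSum weights.

#' Time-varying directed exponential graph
#'
#' Round `t` is the permutation in which client `k` sends its proxy to
#' client `(k + 2^(t mod m)) mod K`, with `m = floor(log2(K - 1)) + 1`, so
#' offsets cycle through 1, 2, 4, ... Each client sends and receives
#' exactly one proxy per round, and any client's information reaches all
#' `K` clients within `ceiling(log2(K))` rounds.
#'
#' @param t Round index (0-based).
#' @param K Number of clients (>= 2).
#' @return A `pfl_commround`: list with the `K x K` permutation matrix `P`
#'   (column- and row-stochastic; `P[k, k']` nonzero means `k` receives
#'   from `k'`) and the round index `t`.
#' @export
exponential_graph <- function(t, K) {
  if (K < 2) stopf("exponential graph requires at least 2 clients")
  m <- floor(log2(K - 1)) + 1
  offset <- 2^(t %% m)
  P <- matrix(0, K, K)
  senders <- 0:(K - 1)
  receivers <- (senders + offset) %% K
  P[cbind(receivers + 1L, senders + 1L)] <- 1
  structure(list(P = P, t = t), class = "pfl_commround")
}

#' Build a communication round from an explicit mixing matrix
#' @param P Nonnegative column-stochastic matrix.
#' @param t Round index.
#' @return A `pfl_commround`.
#' @export
comm_round <- function(P, t = 0L) {
  structure(list(P = P, t = t), class = "pfl_commround")
}

#' One PushSum gossip exchange
#'
#' Applies the mixing matrix to the stacked proxies and the weight vector:
#' `Theta' = P Theta`, `w' = P w`. Column-stochasticity makes the exchange
#' mass-conserving: both the column sums of `Theta` and the total weight
#' are invariant to machine precision.
#'
#' @param Theta Matrix `[K, P]`; row `k` is client `k`'s proxy parameters.
#' @param w Positive PushSum weight vector of length `K`.
#' @param round A `pfl_commround`; its matrix must be column-stochastic
#'   (each column summing to 1 within 1e-9).
#' @return `list(Theta, w)` after mixing.
#' @export
pushsum_mix <- function(Theta, w, round) {
  P <- round$P
  if (any(P < 0)) stopf("mixing matrix must be nonnegative")
  csums <- colSums(P)
  if (any(abs(csums - 1) > 1e-9))
    stopf("mixing matrix is not column-stochastic (column %d sums to %.12f)",
          which.max(abs(csums - 1)), csums[which.max(abs(csums - 1))])
  list(Theta = P %*% Theta, w = as.numeric(P %*% w))
}

#' De-bias a PushSum proxy by its weight
#'
#' The de-biased value `theta_k / w_k` tracks the network average of the
#' initial proxies under repeated mixing.
#'
#' @param proxy_row Parameter vector (one row of `Theta`).
#' @param weight Positive PushSum weight.
#' @return The de-biased parameter vector.
#' @export
debias <- function(proxy_row, weight) {
  if (weight <= 0) stopf("PushSum weight must be positive, got %s",
                         format(weight))
  as.numeric(proxy_row) / weight
}

# --- client state ------------------------------------------------------------

#' Construct one collaborator's state
#'
#' @param id Client index (1-based).
#' @param dataset The client's private `pfl_dataset`.
#' @param proxy Common-architecture proxy classifier (identical spec across
#'   clients).
#' @param private Private classifier (architecture free to differ), or
#'   `NULL` for single-model protocols.
#' @param q Poisson sampling rate used by this client's DP steps.
#' @param sigma Noise multiplier (for the accountant).
#' @param orders Accountant order grid.
#' @return An object of class `pfl_client`.
#' @export
client_state <- function(id, dataset, proxy, private = NULL,
                         q, sigma, orders = default_rdp_orders()) {
  structure(list(
    id = id, dataset = dataset, proxy = proxy, private = private,
    pushsum_weight = 1,
    accountant = accountant_state(q, sigma, orders),
    opt_proxy = make_optimizer(), opt_private = make_optimizer(),
    receipts = list(), dropped = FALSE
  ), class = "pfl_client")
}

# --- local training ----------------------------------------------------------

# One epoch-equivalent of alternating DML steps for a two-model client:
# private (non-DP, mixed gradient with weight alpha) then proxy (DP, weight
# beta). Every privatized release appends one receipt and advances the
# accountant by one step.
train_client_dml <- function(client, config) {
  n <- nrow(client$dataset$x)
  B <- min(config$batch_size, n)
  q <- B / n
  steps <- ceiling(n / B)
  for (s in seq_len(steps)) {
    batch <- poisson_sample(client$dataset, q)
    if (is.null(batch)) next
    # private model: plain mixed-gradient step
    g <- colMeans(mixed_per_example_grads(client$private, client$proxy,
                                          batch, config$mutual$alpha))
    stepped <- opt_step(client$private, g, client$opt_private)
    client$private <- stepped$model
    client$opt_private <- stepped$opt
    # proxy model: DP step
    res <- dp_step(client$proxy, client$private, batch, config$mutual,
                   config$dp, client$opt_proxy, q)
    client$proxy <- res$model
    client$opt_proxy <- res$opt
    client$receipts[[length(client$receipts) + 1L]] <- res$receipt
    client$accountant <- compose(client$accountant, 1L)
  }
  client
}

# One epoch-equivalent of plain DP cross-entropy training on the proxy slot
# (single-model protocols: FedAvg, AvgPush, CWT, Regular, Joint).
train_client_plain_dp <- function(client, config) {
  n <- nrow(client$dataset$x)
  B <- min(config$batch_size, n)
  q <- B / n
  steps <- ceiling(n / B)
  w0 <- mutual_weights(0, 0, diagnostic = TRUE)
  for (s in seq_len(steps)) {
    batch <- poisson_sample(client$dataset, q)
    if (is.null(batch)) next
    res <- dp_step(client$proxy, NULL, batch, w0, config$dp,
                   client$opt_proxy, q)
    client$proxy <- res$model
    client$opt_proxy <- res$opt
    client$receipts[[length(client$receipts) + 1L]] <- res$receipt
    client$accountant <- compose(client$accountant, 1L)
  }
  client
}

mark_dropped <- function(clients, config) {
  if (!is.finite(config$budget_epsilon %||% Inf)) return(clients)
  for (k in seq_along(clients)) {
    if (!clients[[k]]$dropped &&
        check_budget(clients[[k]]$accountant, config$delta,
                     config$budget_epsilon)) {
      clients[[k]]$dropped <- TRUE
    }
  }
  clients
}

# stack active clients' proxy parameters into [K_active, P]
stack_proxies <- function(clients, active) {
  do.call(rbind, lapply(clients[active], function(cl) cl$proxy$params))
}

# --- protocol rounds ---------------------------------------------------------

#' One round of the proxy-sharing protocol
#'
#' Per Algorithm: every active client (1) alternates private and
#' DP-trained proxy updates for one epoch-equivalent of Poisson-sampled
#' steps, (2) sends its proxy parameters and PushSum weight through the
#' round's exponential-graph permutation, and (3) replaces its proxy with
#' the de-biased received aggregate. Clients whose privacy budget is
#' exhausted drop out; the graph is restricted to the remaining clients.
#' With a single active client, gossip is skipped and the round reduces to
#' local mutual learning.
#'
#' @param clients List of `pfl_client` objects (two-model clients).
#' @param t Round index (0-based).
#' @param config Protocol configuration, see [protocol_config()].
#' @return The updated client list.
#' @export
proxyfl_round <- function(clients, t, config) {
  active <- which(!vapply(clients, function(cl) cl$dropped, logical(1)))
  for (k in active) clients[[k]] <- train_client_dml(clients[[k]], config)
  clients <- mark_dropped(clients, config)
  active <- which(!vapply(clients, function(cl) cl$dropped, logical(1)))
  if (length(active) >= 2L) {
    round <- exponential_graph(t, length(active))
    Theta <- stack_proxies(clients, active)
    w <- vapply(clients[active], function(cl) cl$pushsum_weight, numeric(1))
    mixed <- pushsum_mix(Theta, w, round)
    for (i in seq_along(active)) {
      k <- active[i]
      clients[[k]]$proxy <- set_params(clients[[k]]$proxy,
                                       debias(mixed$Theta[i, ], mixed$w[i]))
      clients[[k]]$pushsum_weight <- 1
    }
  }
  clients
}

#' One round of a comparison protocol
#'
#' Implements the five collaborative baselines plus isolated training:
#' `fedavg` (local DP training, then the parameter mean replaces every
#' model), `avgpush` (local DP training, then one PushSum exchange on the
#' exponential graph with de-biased replacement), `cwt` (local DP training,
#' then each model is passed to the next client in a cycle), `fml` (local
#' mutual learning with DP proxies, then the central uniform mean of
#' proxies replaces every proxy), `regular` (local DP training only), and
#' `joint` (a single client on the pooled data; local DP training only).
#' Single-model protocols train with plain DP cross-entropy; `fml` trains
#' like the proxy-sharing protocol but aggregates centrally.
#'
#' @param clients List of `pfl_client` objects.
#' @param t Round index (0-based).
#' @param config Protocol configuration with `method` set.
#' @return The updated client list.
#' @export
baseline_round <- function(clients, t, config) {
  method <- config$method
  two_model <- method == "fml"
  active <- which(!vapply(clients, function(cl) cl$dropped, logical(1)))
  for (k in active) {
    clients[[k]] <- if (two_model) train_client_dml(clients[[k]], config)
    else train_client_plain_dp(clients[[k]], config)
  }
  clients <- mark_dropped(clients, config)
  active <- which(!vapply(clients, function(cl) cl$dropped, logical(1)))
  K <- length(active)
  if (K >= 2L && method %in% c("fedavg", "fml")) {
    check_same_arch(clients[active])
    Theta <- stack_proxies(clients, active)
    avg <- colMeans(Theta)
    for (k in active) clients[[k]]$proxy <- set_params(clients[[k]]$proxy, avg)
  } else if (K >= 2L && method == "avgpush") {
    check_same_arch(clients[active])
    round <- exponential_graph(t, K)
    Theta <- stack_proxies(clients, active)
    w <- vapply(clients[active], function(cl) cl$pushsum_weight, numeric(1))
    mixed <- pushsum_mix(Theta, w, round)
    for (i in seq_len(K)) {
      k <- active[i]
      clients[[k]]$proxy <- set_params(clients[[k]]$proxy,
                                       debias(mixed$Theta[i, ], mixed$w[i]))
      clients[[k]]$pushsum_weight <- 1
    }
  } else if (K >= 2L && method == "cwt") {
    check_same_arch(clients[active])
    Theta <- stack_proxies(clients, active)
    for (i in seq_len(K)) {
      recv <- active[(i %% K) + 1L]   # client i passes its model to i+1
      clients[[recv]]$proxy <- set_params(clients[[recv]]$proxy, Theta[i, ])
    }
  }
  # regular / joint: no communication
  clients
}

check_same_arch <- function(clients) {
  ref <- clients[[1]]$proxy$arch
  for (cl in clients[-1]) {
    a <- cl$proxy$arch
    same <- identical(a$family, ref$family) &&
      identical(a$input_shape, ref$input_shape) &&
      identical(a$n_classes, ref$n_classes) &&
      length(cl$proxy$params) == length(clients[[1]]$proxy$params)
    if (!same)
      stopf("parameter averaging requires structurally identical models")
  }
  invisible(TRUE)
}
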