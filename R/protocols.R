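#' Protocol configuration
#'
#' Bundles every tunable of a federated run. Defaults mirror the benchmark
#' settings of the study conditions: Adam with learning rate 0.001 and
#' weight decay 1e-4, mutual-learning weights alpha = beta = 0.5, clipping
#' C = 1.0 and noise level sigma = 1.0.
#'
#' @param method One of `"proxyfl"`, `"fml"`, `"fedavg"`, `"avgpush"`,
#'   `"cwt"`, `"regular"`, `"joint"`.
#' @param rounds Number of train-communicate rounds (>= 1).
#' @param batch_size Expected Poisson batch size.
#' @param mutual A [mutual_weights()] object.
#' @param dp A [dp_config()] object.
#' @param lr Learning rate.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param weight_decay L2 coefficient.
#' @param delta DP delta for reports and budget checks.
#' @param budget_epsilon Privacy budget; clients drop out when reached
#'   (default `Inf`, never).
#' @param seed Integer seed controlling every source of randomness.
#' @return An object of class `pfl_protocol_config`.
#' @export
protocol_config <- function(method = "proxyfl", rounds = 10,
                            batch_size = 250,
                            mutual = mutual_weights(0.5, 0.5),
                            dp = dp_config(clip_C = 1.0, sigma = 1.0),
                            lr = 0.001, optimizer = "adam",
                            weight_decay = 1e-4, delta = 1e-5,
                            budget_epsilon = Inf, seed = 1) {
  method <- match.arg(method, c("proxyfl", "fml", "fedavg", "avgpush",
                                "cwt", "regular", "joint"))
  if (rounds < 1) stopf("rounds must be >= 1")
  structure(list(method = method, rounds = as.integer(rounds),
                 batch_size = batch_size, mutual = mutual, dp = dp,
                 lr = lr, optimizer = optimizer,
                 weight_decay = weight_decay, delta = delta,
                 budget_epsilon = budget_epsilon, seed = as.integer(seed)),
            class = "pfl_protocol_config")
}

# Build the client list for a protocol. Shared-architecture models (all
# proxies; all single-model baselines) start from one common seed so that
# parameter averaging is meaningful; private models get per-client seeds.
init_clients <- function(datasets, config, proxy_arch, private_arch = NULL) {
  two_model <- config$method %in% c("proxyfl", "fml")
  if (config$method == "joint") {
    pooled <- pool_datasets(datasets)
    datasets <- list(pooled)
  }
  K <- length(datasets)
  lapply(seq_len(K), function(k) {
    n <- nrow(datasets[[k]]$x)
    B <- min(config$batch_size, n)
    proxy <- init_classifier(proxy_arch, seed = config$seed)
    private <- if (two_model) {
      arch_k <- if (is.list(private_arch) && !inherits(private_arch, "pfl_arch"))
        private_arch[[k]] else (private_arch %||% proxy_arch)
      init_classifier(arch_k, seed = config$seed + 1000L * k)
    } else NULL
    cl <- client_state(k, datasets[[k]], proxy, private,
                       q = B / n, sigma = config$dp$sigma)
    cl$opt_proxy <- make_optimizer(config$optimizer, config$lr,
                                   config$weight_decay)
    cl$opt_private <- make_optimizer(config$optimizer, config$lr,
                                     config$weight_decay)
    cl
  })
}

#' Pool several client datasets into one
#' @param datasets List of `pfl_dataset` objects with matching shapes.
#' @return A single `pfl_dataset`.
#' @export
pool_datasets <- function(datasets) {
  structure(list(
    x = do.call(rbind, lapply(datasets, function(d) d$x)),
    y = unlist(lapply(datasets, function(d) d$y), use.names = FALSE),
    n_classes = datasets[[1]]$n_classes,
    input_shape = datasets[[1]]$input_shape
  ), class = "pfl_dataset")
}

#' Run a full federated protocol
#'
#' Seeds the RNG once from `config$seed`, builds the clients, then
#' alternates training and communication for `config$rounds` rounds,
#' evaluating every client's model(s) on the shared IID test set after each
#' round. Fully reproducible: the same `(config, datasets, test_set)` give
#' bit-identical histories.
#'
#' @param config A [protocol_config()].
#' @param datasets List of per-client `pfl_dataset` objects (ignored length
#'   for `"joint"`, which pools them).
#' @param test_set Shared held-out `pfl_dataset`.
#' @param proxy_arch Architecture for proxies / single models (one
#'   `pfl_arch`, identical across clients).
#' @param private_arch Architecture for private models (a `pfl_arch`, a
#'   list of one per client, or `NULL` to reuse `proxy_arch`); two-model
#'   methods only.
#' @param eval_every Evaluate every this many rounds (default 1).
#' @return `list(metrics, clients)`: `metrics` is a data.frame with columns
#'   round, client, model, accuracy, macro_accuracy, epsilon; `clients` is
#'   the final client list.
#' @export
run_protocol <- function(config, datasets, test_set, proxy_arch,
                         private_arch = NULL, eval_every = 1L) {
  set.seed(config$seed)
  clients <- init_clients(datasets, config, proxy_arch, private_arch)
  two_model <- config$method %in% c("proxyfl", "fml")
  metrics <- list()

  record <- function(round_idx) {
    for (cl in clients) {
      eps <- to_epsilon(cl$accountant, config$delta)$epsilon
      if (two_model) {
        mp <- evaluate(cl$private, test_set)
        metrics[[length(metrics) + 1L]] <<- data.frame(
          round = round_idx, client = cl$id, model = "private",
          accuracy = mp[["accuracy"]], macro_accuracy = mp[["macro_accuracy"]],
          epsilon = eps)
      }
      mx <- evaluate(cl$proxy, test_set)
      metrics[[length(metrics) + 1L]] <<- data.frame(
        round = round_idx, client = cl$id,
        model = if (two_model) "proxy" else "model",
        accuracy = mx[["accuracy"]], macro_accuracy = mx[["macro_accuracy"]],
        epsilon = eps)
    }
  }

  record(0L)
  if (config$rounds >= 1L) {
    for (t in 0:(config$rounds - 1L)) {
      clients <- if (config$method == "proxyfl")
        proxyfl_round(clients, t, config)
      else baseline_round(clients, t, config)
      if ((t + 1L) %% eval_every == 0L || t == config$rounds - 1L)
        record(t + 1L)
    }
  }
  list(metrics = do.call(rbind, metrics), clients = clients)
}
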