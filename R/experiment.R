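# Reproducible experiment driver: config parsing, seed control, metrics
# logging, and cross-run summaries.

config_schema <- list(
  method = "character", rounds = "numeric", clients = "numeric",
  seeds = "numeric",
  data = list(n_classes = "numeric", dim = "numeric",
              per_client_n = "numeric", partition = "character"),
  train = list(batch_size = "numeric")
)

validate_config <- function(cfg) {
  check <- function(schema, node, path) {
    for (key in names(schema)) {
      here <- if (path == "") key else paste(path, key, sep = ".")
      if (is.null(node[[key]]))
        stopf("config is missing required key '%s'", here)
      if (is.list(schema[[key]])) {
        check(schema[[key]], node[[key]], here)
      } else {
        ok <- switch(schema[[key]],
                     numeric = is.numeric(node[[key]]),
                     character = is.character(node[[key]]),
                     TRUE)
        if (!ok) stopf("config key '%s' must be %s", here, schema[[key]])
      }
    }
  }
  check(config_schema, cfg, "")
  ok_methods <- c("proxyfl", "fml", "fedavg", "avgpush", "cwt", "regular",
                  "joint")
  if (!cfg$method %in% ok_methods)
    stopf("config key 'method' must be one of: %s",
          paste(ok_methods, collapse = ", "))
  ok_part <- c("skewed", "dirichlet", "iid")
  if (!cfg$data$partition %in% ok_part)
    stopf("config key 'data.partition' must be one of: %s",
          paste(ok_part, collapse = ", "))
  invisible(cfg)
}

read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_config(cfg)
}

build_arch_from_config <- function(cfg, which = c("proxy", "private")) {
  which <- match.arg(which)
  hidden <- cfg$model[[paste0(which, "_hidden")]] %||%
    cfg$model$proxy_hidden %||% c(32)
  arch_spec("mlp", input_shape = cfg$data$dim, hidden = hidden,
            n_classes = cfg$data$n_classes)
}

# Per-(seed, sweep value) data: one pooled distribution from which both the
# client partition and the shared IID test set are drawn, mirroring the
# benchmark setting where skewed clients must generalize to an IID test set
# of the same task.
build_run_data <- function(cfg, seed, p_major = NULL) {
  d <- cfg$data
  K <- cfg$clients
  test_npc <- d$test_n_per_class %||% 100
  # pool large enough for every client's quota, the test set, plus slack
  need <- ceiling(1.3 * K * d$per_client_n / d$n_classes) +
    d$per_client_n + test_npc
  pool_all <- make_synthetic(d$n_classes, d$dim, need,
                             class_separation = d$class_separation %||% 3,
                             noise_sd = d$noise_sd %||% 1,
                             seed = seed + 10000L)
  # examples are already shuffled: the head is an IID draw from the pool
  n_test <- test_npc * d$n_classes
  test <- subset_dataset(pool_all, seq_len(n_test))
  pool <- subset_dataset(pool_all, (n_test + 1L):nrow(pool_all$x))
  assignments <- switch(d$partition,
    skewed = partition_skewed(pool, K, p_major %||% d$p_major,
                              d$per_client_n, seed = seed + 20000L)$assignments,
    dirichlet = partition_dirichlet(pool, K, d$concentration %||% 0.5,
                                    seed = seed + 20000L)$assignments,
    iid = {
      idx <- with_seed(seed + 20000L, shuffle(seq_along(pool$y)))
      split(idx[seq_len(K * d$per_client_n)],
            rep(seq_len(K), each = d$per_client_n))
    })
  datasets <- lapply(assignments, function(ix) subset_dataset(pool, ix))
  list(datasets = datasets, test = test)
}

config_to_protocol <- function(cfg, seed) {
  tr <- cfg$train
  protocol_config(
    method = cfg$method, rounds = cfg$rounds,
    batch_size = tr$batch_size,
    mutual = mutual_weights(tr$alpha %||% 0.5, tr$beta %||% 0.5),
    dp = dp_config(clip_C = tr$clip_C %||% 1.0, sigma = tr$sigma %||% 1.0),
    lr = tr$lr %||% 0.001, optimizer = tr$optimizer %||% "adam",
    weight_decay = tr$weight_decay %||% 1e-4,
    delta = tr$delta %||% 1e-5,
    budget_epsilon = tr$budget_epsilon %||% Inf,
    seed = seed
  )
}

#' Run a configured experiment
#'
#' Reads a YAML or JSON config, runs the configured protocol once per seed
#' (and once per `data.p_major` value when that key is a vector, emitting
#' one metrics block per setting), and writes `metrics.csv` plus a
#' `manifest.json` sufficient to replay the run.
#'
#' @param config_path Path to the config file.
#' @param out_dir Output directory (default: `runs/<config name>`).
#' @return Invisibly, the manifest as a list (with `metrics_path`).
#' @export
run_experiment <- function(config_path, out_dir = NULL) {
  cfg <- read_config(config_path)
  out_dir <- out_dir %||% cfg$out_dir %||%
    file.path("runs", sub("\\.(ya?ml|json)$", "", basename(config_path)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- as.integer(cfg$seeds)
  sweep <- if (cfg$data$partition == "skewed") cfg$data$p_major else NA
  all_metrics <- list()
  final <- list()
  for (pv in sweep) {
    for (seed in seeds) {
      dat <- build_run_data(cfg, seed, p_major = if (is.na(pv)) NULL else pv)
      pconf <- config_to_protocol(cfg, seed)
      arch_p <- build_arch_from_config(cfg, "proxy")
      arch_f <- if (cfg$method %in% c("proxyfl", "fml"))
        build_arch_from_config(cfg, "private") else NULL
      res <- run_protocol(pconf, dat$datasets, dat$test, arch_p, arch_f)
      m <- res$metrics
      m$seed <- seed
      m$method <- cfg$method
      if (!is.na(pv)) m$p_major <- pv
      all_metrics[[length(all_metrics) + 1L]] <- m
      fin <- m[m$round == max(m$round), ]
      final[[length(final) + 1L]] <- fin
    }
  }
  metrics <- do.call(rbind, all_metrics)
  metrics_path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(metrics, metrics_path, row.names = FALSE)
  manifest <- list(
    config = cfg, seeds = seeds,
    final_metrics = do.call(rbind, final),
    package_version = as.character(utils::packageVersion("proxyfl")),
    metrics_path = metrics_path
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  invisible(manifest)
}

#' Summarize completed runs
#'
#' Aggregates metrics across seeds and clients: for every method, model and
#' round (and sweep setting, when present), the mean and standard deviation
#' of accuracy and macro-accuracy.
#'
#' @param run_dirs Character vector of directories written by
#'   [run_experiment()].
#' @return A data.frame of per-round summaries.
#' @export
summarize_runs <- function(run_dirs) {
  if (length(run_dirs) < 1L) stopf("at least one run directory is required")
  parts <- lapply(run_dirs, function(d) {
    p <- file.path(d, "metrics.csv")
    if (!file.exists(p)) stopf("no metrics.csv in '%s'", d)
    utils::read.csv(p, stringsAsFactors = FALSE)
  })
  manifests <- lapply(run_dirs, function(d) {
    p <- file.path(d, "manifest.json")
    if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else NULL
  })
  rounds_of <- function(m) if (is.null(m)) NA else m$config$rounds
  r0 <- rounds_of(manifests[[1]])
  for (m in manifests[-1]) {
    if (!identical(rounds_of(m), r0))
      stopf("runs have mismatched configs (rounds differ) and cannot be pooled")
  }
  metrics <- do.call(rbind, parts)
  keys <- intersect(c("method", "model", "round", "p_major"), names(metrics))
  groups <- split(metrics, metrics[keys], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    row <- g[1, keys, drop = FALSE]
    row$mean_accuracy <- mean(g$accuracy)
    row$sd_accuracy <- stats::sd(g$accuracy)
    if (nrow(g) == 1L) row$sd_accuracy <- 0
    row$mean_macro_accuracy <- mean(g$macro_accuracy)
    row$sd_macro_accuracy <- if (nrow(g) == 1L) 0 else stats::sd(g$macro_accuracy)
    row$n <- nrow(g)
    row
  }))
  rownames(out) <- NULL
  out[order(out$method, out$model, out$round), ]
}
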