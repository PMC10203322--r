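# Shared fixtures and independent oracles for the test suite.

tiny_mlp_arch <- function(d = 3, hidden = c(4), classes = 3) {
  arch_spec("mlp", input_shape = d, hidden = hidden, n_classes = classes)
}

tiny_cnn_arch <- function() {
  arch_spec("cnn", input_shape = c(5, 5, 1),
            hidden = list(conv_layer(2, 3, 2)), n_classes = 3)
}

random_batch <- function(arch, B, seed) {
  set.seed(seed)
  make_batch(matrix(rnorm(B * prod(arch$input_shape)), B),
             sample(0:(arch$n_classes - 1L), B, replace = TRUE),
             arch$n_classes)
}

# Central finite differences of a per-example loss w.r.t. all parameters:
# the independent oracle for per-example gradient rows.
fd_grads <- function(model, batch, loss, h = 1e-5) {
  P <- length(model$params)
  B <- nrow(batch$x)
  G <- matrix(0, B, P)
  for (j in seq_len(P)) {
    up <- model; up$params[j] <- up$params[j] + h
    dn <- model; dn$params[j] <- dn$params[j] - h
    lu <- loss$value(forward_probs(up, batch$x), batch$y)
    ld <- loss$value(forward_probs(dn, batch$x), batch$y)
    G[, j] <- (lu - ld) / (2 * h)
  }
  G
}

# Hand-rolled MLP forward pass from the flat vector and layout, written
# with explicit matrix arithmetic, independent of forward_probs internals.
manual_mlp_forward <- function(model, x) {
  layout <- model$layout
  p <- model$params
  a <- x
  layers <- model$arch$layers
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    W <- matrix(p[layout[[paste0(l$name, ".W")]]], l$d_out, l$d_in)
    b <- p[layout[[paste0(l$name, ".b")]]]
    z <- a %*% t(W) + matrix(b, nrow(a), l$d_out, byrow = TRUE)
    a <- if (i < length(layers)) pmax(z, 0) else z
  }
  ez <- exp(a - apply(a, 1, max))
  ez / rowSums(ez)
}

# scaled-down skewed-label federated task shared by protocol tests:
# 10-class Gaussian blobs, 8 clients, p_major skew, IID test set from the
# same pool
skewed_task <- function(seed, K = 8, n = 200, dim = 16, sep = 3,
                        p_major = 0.8, test_n = 1000) {
  pool_all <- make_synthetic(10, dim, ceiling(1.3 * K * n / 10) + n + 100,
                             class_separation = sep, noise_sd = 1,
                             seed = seed + 10000)
  test <- subset_dataset(pool_all, seq_len(test_n))
  pool <- subset_dataset(pool_all, (test_n + 1):nrow(pool_all$x))
  part <- partition_skewed(pool, K, p_major, n, seed = seed + 20000)
  list(datasets = lapply(part$assignments,
                         function(ix) subset_dataset(pool, ix)),
       test = test)
}
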