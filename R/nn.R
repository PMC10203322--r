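#' Mini-batch container
#'
#' @param x Numeric matrix `[B, prod(input_shape)]` or array whose first
#'   dimension indexes examples.
#' @param y Integer labels in `[0, n_classes)`, one per example.
#' @param n_classes Optional; when given, labels are range-checked.
#' @return A list of class `pfl_batch` with matrix `x` and integer `y`.
#' @export
make_batch <- function(x, y, n_classes = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (length(dim(x)) > 2L) {
    d <- dim(x)
    x <- matrix(x, nrow = d[1L])
  }
  y <- as.integer(y)
  if (nrow(x) != length(y))
    stopf("batch size mismatch: %d rows of x vs %d labels", nrow(x), length(y))
  if (nrow(x) < 1L) stopf("batch must contain at least one example")
  if (!is.null(n_classes) && (any(y < 0L) || any(y >= n_classes)))
    stopf("labels must lie in [0, %d)", n_classes)
  structure(list(x = x, y = y), class = "pfl_batch")
}

# reshape one row of the flattened batch matrix back to [h, w, c]
row_to_image <- function(xrow, shape) array(xrow, dim = shape)

# --- forward -----------------------------------------------------------------

# Forward pass over a batch. Returns list(probs, logits) and, with
# keep_cache = TRUE, per-layer activations needed for backprop.
forward_full <- function(model, x, keep_cache = FALSE) {
  arch <- model$arch
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (length(dim(x)) > 2L) x <- matrix(x, nrow = dim(x)[1L])
  if (ncol(x) != prod(arch$input_shape))
    stopf("input has %d features, arch expects %d", ncol(x),
          prod(arch$input_shape))
  if (arch$family == "mlp") forward_mlp(model, x, keep_cache)
  else forward_cnn(model, x, keep_cache)
}

forward_mlp <- function(model, x, keep_cache) {
  p <- model$params
  a <- x
  acts <- if (keep_cache) list(a) else NULL   # acts[[i]] = input to layer i
  masks <- if (keep_cache) list() else NULL   # relu derivative masks
  for (l in model$arch$layers) {
    W <- matrix(p[l$w_idx], nrow = l$d_out, ncol = l$d_in)
    b <- p[l$b_idx]
    z <- tcrossprod(a, W)                     # [B, d_out]
    z <- sweep(z, 2L, b, "+")
    if (l$act == "relu") {
      if (keep_cache) masks[[length(masks) + 1L]] <- (z > 0)
      a <- z * (z > 0)
    } else {
      a <- z
    }
    if (keep_cache) acts[[length(acts) + 1L]] <- a
  }
  probs <- softmax_rows(a)
  list(probs = probs, logits = a, acts = acts, masks = masks)
}

forward_cnn <- function(model, x, keep_cache) {
  B <- nrow(x)
  arch <- model$arch
  logits <- matrix(NA_real_, B, arch$n_classes)
  caches <- if (keep_cache) vector("list", B) else NULL
  for (e in seq_len(B)) {
    res <- forward_cnn_one(model, x[e, ], keep_cache)
    logits[e, ] <- res$logits
    if (keep_cache) caches[[e]] <- res
  }
  list(probs = softmax_rows(logits), logits = logits, caches = caches)
}

forward_cnn_one <- function(model, xrow, keep_cache) {
  p <- model$params
  a <- row_to_image(xrow, model$arch$input_shape)
  cols_cache <- list(); mask_cache <- list(); in_cache <- list()
  for (l in model$arch$layers) {
    if (l$type == "conv") {
      cols <- im2col(a, l$kernel, l$stride)     # [k*k*c, oh*ow]
      W <- matrix(p[l$w_idx], nrow = l$out_c)
      z <- W %*% cols + p[l$b_idx]              # [oc, oh*ow]
      mask <- z > 0
      a <- array(t(z * mask), dim = c(l$out_h, l$out_w, l$out_c))
      if (keep_cache) {
        cols_cache[[l$name]] <- cols
        mask_cache[[l$name]] <- mask
      }
    } else {
      flat <- as.numeric(a)
      W <- matrix(p[l$w_idx], nrow = l$d_out, ncol = l$d_in)
      z <- as.numeric(W %*% flat + p[l$b_idx])
      if (keep_cache) in_cache[[l$name]] <- flat
      a <- z
    }
  }
  list(logits = a, cols = cols_cache, masks = mask_cache, dense_in = in_cache)
}

# im2col for a [h, w, c] array: columns are receptive fields, ordered by
# output position (column-major over [oh, ow]); rows ordered (kh, kw, c)
# column-major to match array flattening.
im2col <- function(x, k, stride) {
  h <- dim(x)[1]; w <- dim(x)[2]; ch <- dim(x)[3]
  oh <- (h - k) %/% stride + 1L
  ow <- (w - k) %/% stride + 1L
  out <- matrix(0, k * k * ch, oh * ow)
  col <- 0L
  for (j in seq_len(ow)) {
    cj <- (j - 1L) * stride
    for (i in seq_len(oh)) {
      ci <- (i - 1L) * stride
      col <- col + 1L
      out[, col] <- as.numeric(x[ci + seq_len(k), cj + seq_len(k), ,
                                 drop = FALSE])
    }
  }
  out
}

col2im <- function(cols, shape, k, stride) {
  h <- shape[1]; w <- shape[2]; ch <- shape[3]
  oh <- (h - k) %/% stride + 1L
  ow <- (w - k) %/% stride + 1L
  out <- array(0, dim = shape)
  col <- 0L
  for (j in seq_len(ow)) {
    cj <- (j - 1L) * stride
    for (i in seq_len(oh)) {
      ci <- (i - 1L) * stride
      col <- col + 1L
      patch <- array(cols[, col], dim = c(k, k, ch))
      out[ci + seq_len(k), cj + seq_len(k), ] <-
        out[ci + seq_len(k), cj + seq_len(k), , drop = FALSE] + patch
    }
  }
  out
}

#' Class probabilities for a batch of inputs
#'
#' @param model A `pfl_classifier`.
#' @param x Input matrix `[B, prod(input_shape)]` (or array with leading
#'   batch dimension).
#' @return Probability matrix `[B, n_classes]`; each row is a simplex point.
#' @export
forward_probs <- function(model, x) forward_full(model, x, FALSE)$probs

# --- per-example gradients ---------------------------------------------------

#' Loss specifications for per-example gradients
#'
#' A loss spec carries the per-example loss value and its gradient with
#' respect to the classifier logits; backpropagation through the network is
#' shared. `loss_ce()` is plain cross-entropy. `loss_mixed()` is the mutual
#' learning gradient `(1 - weight) * CE + weight * KL(model || peer)`, with
#' the peer's predictions `q_rows` treated as constants.
#'
#' @param weight Mixing weight in `[0, 1]` on the KL term.
#' @param q_rows Peer probability rows aligned with the batch.
#' @return A list with functions `value(probs, y)` and `dlogits(probs, y)`.
#' @export
loss_ce <- function() {
  list(
    value = function(probs, y) ce_loss(probs, y),
    dlogits = function(probs, y) probs - onehot_rows(y, ncol(probs))
  )
}

#' @rdname loss_ce
#' @export
loss_mixed <- function(weight, q_rows) {
  if (weight < 0 || weight > 1) stopf("weight must lie in [0, 1]")
  list(
    value = function(probs, y) {
      (1 - weight) * ce_loss(probs, y) + weight * kl_loss(probs, q_rows)
    },
    dlogits = function(probs, y) {
      g <- (1 - weight) * (probs - onehot_rows(y, ncol(probs)))
      if (weight > 0) {
        ell <- log(pmax(probs, PROB_FLOOR)) - log(pmax(q_rows, PROB_FLOOR))
        kl <- rowSums(probs * ell)
        g <- g + weight * probs * (ell - kl)
      }
      g
    }
  )
}

#' Per-example parameter gradients
#'
#' Computes one gradient row per example: row `i` is the gradient of the
#' loss on example `i` alone with respect to all model parameters. The mean
#' over rows equals the gradient of the mean batch loss, which is the
#' quantity DP-SGD clips per example before aggregation.
#'
#' @param model A `pfl_classifier`.
#' @param batch A `pfl_batch`.
#' @param loss A loss spec ([loss_ce()] or [loss_mixed()]).
#' @return Matrix `[B, n_params]` of per-example gradients.
#' @export
per_example_grads <- function(model, batch, loss = loss_ce()) {
  fw <- forward_full(model, batch$x, keep_cache = TRUE)
  vals <- loss$value(fw$probs, batch$y)
  if (any(!is.finite(vals)))
    stopf("non-finite loss at example %d", which(!is.finite(vals))[1L])
  dlog <- loss$dlogits(fw$probs, batch$y)
  if (model$arch$family == "mlp") backward_mlp(model, fw, dlog)
  else backward_cnn(model, fw, dlog, batch)
}

backward_mlp <- function(model, fw, dlog) {
  layers <- model$arch$layers
  B <- nrow(dlog)
  P <- length(model$params)
  G <- matrix(0, B, P)
  delta <- dlog                                  # [B, d_out of last layer]
  p <- model$params
  nmask <- length(fw$masks)
  for (li in rev(seq_along(layers))) {
    l <- layers[[li]]
    a_in <- fw$acts[[li]]                        # input activation [B, d_in]
    # per-example dW rows: vec(W) is column-major [d_out, d_in] ->
    # index (i_in - 1) * d_out + i_out
    A_big <- a_in[, rep(seq_len(l$d_in), each = l$d_out), drop = FALSE]
    D_big <- delta[, rep(seq_len(l$d_out), times = l$d_in), drop = FALSE]
    G[, l$w_idx] <- A_big * D_big
    G[, l$b_idx] <- delta
    if (li > 1L) {
      W <- matrix(p[l$w_idx], nrow = l$d_out, ncol = l$d_in)
      delta <- (delta %*% W) * fw$masks[[nmask]]
      nmask <- nmask - 1L
    }
  }
  G
}

backward_cnn <- function(model, fw, dlog, batch) {
  layers <- model$arch$layers
  B <- nrow(dlog)
  G <- matrix(0, B, length(model$params))
  p <- model$params
  for (e in seq_len(B)) {
    cache <- fw$caches[[e]]
    g <- numeric(length(model$params))
    # dense head
    for (li in rev(seq_along(layers))) {
      l <- layers[[li]]
      if (l$type == "dense") {
        delta <- dlog[e, ]
        flat <- cache$dense_in[[l$name]]
        g[l$w_idx] <- as.numeric(outer(delta, flat))  # column-major [out, in]
        g[l$b_idx] <- delta
        W <- matrix(p[l$w_idx], nrow = l$d_out, ncol = l$d_in)
        da <- as.numeric(crossprod(W, delta))
      } else {
        # reshape upstream gradient to [oh*ow, oc] then [oc, oh*ow]
        dz <- t(matrix(da, nrow = l$out_h * l$out_w, ncol = l$out_c))
        dz <- dz * cache$masks[[l$name]]
        cols <- cache$cols[[l$name]]
        g[l$w_idx] <- as.numeric(tcrossprod(dz, cols))  # [oc, k*k*c]
        g[l$b_idx] <- rowSums(dz)
        W <- matrix(p[l$w_idx], nrow = l$out_c)
        dcols <- crossprod(W, dz)                        # [k*k*c, oh*ow]
        da <- as.numeric(col2im(dcols, c(l$in_h, l$in_w, l$in_c),
                                l$kernel, l$stride))
      }
    }
    G[e, ] <- g
  }
  G
}
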