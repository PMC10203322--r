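#' Architecture specification for a small classifier
#'
#' Describes either a multilayer perceptron (`family = "mlp"`) or a small
#' convolutional network (`family = "cnn"`). Two classifiers can exchange
#' parameters (gossip, averaging) only when their specs are structurally
#' identical; private models are free to differ across clients.
#'
#' @param family `"mlp"` or `"cnn"`.
#' @param input_shape Integer vector: feature dimension for an MLP (a single
#'   number, or a shape that is flattened), or `c(height, width, channels)`
#'   for a CNN.
#' @param hidden For an MLP, an integer vector of hidden-layer widths
#'   (possibly empty). For a CNN, a list of convolution descriptors created
#'   by [conv_layer()]; the network ends with a dense softmax head over the
#'   flattened final feature map.
#' @param n_classes Number of classes (>= 2).
#' @return An object of class `pfl_arch`.
#' @examples
#' arch_spec("mlp", input_shape = 16, hidden = c(32, 32), n_classes = 10)
#' @export
arch_spec <- function(family = c("mlp", "cnn"), input_shape, hidden = NULL,
                      n_classes) {
  family <- match.arg(family)
  if (!is.numeric(n_classes) || length(n_classes) != 1L || n_classes < 2)
    stopf("n_classes must be a single integer >= 2, got %s", format(n_classes))
  n_classes <- as.integer(n_classes)
  input_shape <- as.integer(input_shape)
  if (any(input_shape <= 0L)) stopf("input_shape entries must be positive")

  if (family == "mlp") {
    hidden <- as.integer(hidden %||% integer(0))
    if (any(hidden <= 0L)) stopf("hidden widths must be positive")
  } else {
    if (length(input_shape) != 3L)
      stopf("cnn input_shape must be c(height, width, channels)")
    if (is.null(hidden) || !is.list(hidden) || length(hidden) == 0L)
      stopf("cnn hidden must be a non-empty list of conv_layer() descriptors")
    for (h in hidden) {
      if (!inherits(h, "pfl_conv_layer"))
        stopf("cnn hidden entries must be created by conv_layer()")
    }
  }
  a <- structure(
    list(family = family, input_shape = input_shape, hidden = hidden,
         n_classes = n_classes),
    class = "pfl_arch"
  )
  a$layers <- compile_arch(a)
  a
}

#' Convolution layer descriptor
#'
#' @param channels Output channels (positive integer).
#' @param kernel Square kernel size.
#' @param stride Stride (default 1). Valid (no) padding is used.
#' @return An object of class `pfl_conv_layer`.
#' @export
conv_layer <- function(channels, kernel, stride = 1L) {
  if (channels <= 0) stopf("channels must be positive, got %s", channels)
  if (kernel <= 0) stopf("kernel must be positive, got %s", kernel)
  if (stride <= 0) stopf("stride must be positive, got %s", stride)
  structure(list(channels = as.integer(channels), kernel = as.integer(kernel),
                 stride = as.integer(stride)),
            class = "pfl_conv_layer")
}

# Resolve an arch into concrete layer descriptors with dimensions and
# parameter slots. Dense weights are [out, in]; conv weights are
# [out_channels, kernel*kernel*in_channels] (im2col layout).
compile_arch <- function(arch) {
  layers <- list()
  if (arch$family == "mlp") {
    d <- prod(arch$input_shape)
    widths <- c(arch$hidden, arch$n_classes)
    for (i in seq_along(widths)) {
      layers[[i]] <- list(
        type = "dense", d_in = d, d_out = widths[i],
        act = if (i < length(widths)) "relu" else "none",
        name = sprintf("dense%d", i)
      )
      d <- widths[i]
    }
  } else {
    h <- arch$input_shape[1]; w <- arch$input_shape[2]; ch <- arch$input_shape[3]
    for (i in seq_along(arch$hidden)) {
      cv <- arch$hidden[[i]]
      if (cv$kernel > h || cv$kernel > w)
        stopf("conv layer %d: kernel %d exceeds input %dx%d", i, cv$kernel, h, w)
      oh <- (h - cv$kernel) %/% cv$stride + 1L
      ow <- (w - cv$kernel) %/% cv$stride + 1L
      layers[[length(layers) + 1L]] <- list(
        type = "conv", in_h = h, in_w = w, in_c = ch,
        kernel = cv$kernel, stride = cv$stride, out_c = cv$channels,
        out_h = oh, out_w = ow, act = "relu",
        name = sprintf("conv%d", i)
      )
      h <- oh; w <- ow; ch <- cv$channels
    }
    layers[[length(layers) + 1L]] <- list(
      type = "dense", d_in = h * w * ch, d_out = arch$n_classes, act = "none",
      name = "head"
    )
  }
  # assign flat parameter slots: W then b per layer, W stored column-major
  pos <- 0L
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    nw <- as.integer(if (l$type == "dense") l$d_in * l$d_out else
      l$out_c * l$kernel * l$kernel * l$in_c)
    nb <- as.integer(if (l$type == "dense") l$d_out else l$out_c)
    layers[[i]]$w_idx <- pos + seq_len(nw); pos <- pos + nw
    layers[[i]]$b_idx <- pos + seq_len(nb); pos <- pos + nb
  }
  attr(layers, "n_params") <- pos
  layers
}

#' Number of parameters implied by an architecture
#' @param arch A `pfl_arch`.
#' @return Integer parameter count.
#' @export
param_count <- function(arch) attr(arch$layers, "n_params")

#' Flat-parameter layout map
#'
#' @param arch A `pfl_arch`.
#' @return Named list mapping layer slot names (e.g. `"dense1.W"`) to index
#'   ranges into the flat parameter vector; ranges are disjoint and cover it.
#' @export
param_layout <- function(arch) {
  out <- list()
  for (l in arch$layers) {
    out[[paste0(l$name, ".W")]] <- l$w_idx
    out[[paste0(l$name, ".b")]] <- l$b_idx
  }
  out
}

#' Initialize a classifier
#'
#' Parameters are drawn from a fan-in-scaled (He) normal scheme, as a
#' deterministic function of `(arch, seed)`: the same pair always yields a
#' bit-identical parameter vector.
#'
#' @param arch A `pfl_arch`.
#' @param seed Integer seed.
#' @param init `"he"` (default) or `"zero"` (diagnostic; yields uniform
#'   class probabilities).
#' @return An object of class `pfl_classifier` with elements `arch`,
#'   `params` (flat numeric vector) and `layout`.
#' @export
init_classifier <- function(arch, seed, init = c("he", "zero")) {
  init <- match.arg(init)
  if (!inherits(arch, "pfl_arch")) stopf("arch must be a pfl_arch")
  n <- param_count(arch)
  params <- numeric(n)
  if (init == "he") {
    params <- with_seed(as.integer(seed), {
      p <- numeric(n)
      for (l in arch$layers) {
        fan_in <- if (l$type == "dense") l$d_in else l$kernel^2 * l$in_c
        sd <- sqrt(2 / fan_in)
        p[l$w_idx] <- stats::rnorm(length(l$w_idx), sd = sd)
        # biases stay zero
      }
      p
    })
  }
  structure(list(arch = arch, params = params, layout = param_layout(arch)),
            class = "pfl_classifier")
}

#' @export
print.pfl_arch <- function(x, ...) {
  cat(sprintf("<pfl_arch %s> input %s -> %d classes, %d parameters\n",
              x$family, paste(x$input_shape, collapse = "x"),
              x$n_classes, param_count(x)))
  invisible(x)
}

#' @export
print.pfl_classifier <- function(x, ...) {
  cat(sprintf("<pfl_classifier> %s, %d parameters\n", x$arch$family,
              length(x$params)))
  invisible(x)
}

#' Replace a classifier's flat parameter vector
#' @param model A `pfl_classifier`.
#' @param params Numeric vector of matching length.
#' @return The updated classifier.
#' @export
set_params <- function(model, params) {
  if (length(params) != length(model$params))
    stopf("parameter length mismatch: %d vs %d", length(params),
          length(model$params))
  model$params <- as.numeric(params)
  model
}

#' Save / load a parameter checkpoint
#'
#' Checkpoints are plain text: one parameter per line, with a JSON sidecar
#' (`<path>.layout.json`) recording the architecture and layout manifest.
#'
#' @param model A `pfl_classifier`.
#' @param path File path for the flat parameter array.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the parameter vector with the manifest as attribute `"manifest"`.
#' @export
save_checkpoint <- function(model, path) {
  writeLines(format(model$params, digits = 17, scientific = TRUE, trim = TRUE),
             path)
  manifest <- list(
    family = model$arch$family,
    input_shape = model$arch$input_shape,
    n_classes = model$arch$n_classes,
    n_params = length(model$params),
    layout = lapply(model$layout, function(ix) c(min(ix), max(ix)))
  )
  jsonlite::write_json(manifest, paste0(path, ".layout.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  params <- as.numeric(readLines(path))
  mpath <- paste0(path, ".layout.json")
  if (file.exists(mpath)) {
    attr(params, "manifest") <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  }
  params
}
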