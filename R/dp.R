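#' Differential-privacy configuration for proxy training
#'
#' @param clip_C Positive L2 clipping threshold applied to each per-example
#'   gradient.
#' @param sigma Noise multiplier; the Gaussian noise added to the clipped
#'   gradient sum has per-coordinate standard deviation `sigma * clip_C`.
#'   `sigma = 0` is permitted for oracle/degenerate-limit checks only and
#'   provides no privacy.
#' @param enabled Whether DP steps may run at all. Private models never pass
#'   through the DP pipeline; [dp_step()] refuses to run when disabled.
#' @return An object of class `pfl_dp_config`.
#' @export
dp_config <- function(clip_C = 1.0, sigma = 1.0, enabled = TRUE) {
  if (clip_C <= 0) stopf("clip_C must be positive, got %s", format(clip_C))
  if (sigma < 0) stopf("sigma must be nonnegative, got %s", format(sigma))
  structure(list(clip_C = clip_C, sigma = sigma, enabled = isTRUE(enabled)),
            class = "pfl_dp_config")
}

#' Clip per-example gradient rows to an L2 ball
#'
#' Row `i` is scaled by `1 / max(1, ||row_i|| / C)`: rows with norm at most
#' `C` pass through unchanged, larger rows are rescaled onto the sphere of
#' radius `C` while keeping their direction.
#'
#' @param grads Matrix `[B, P]` of per-example gradients.
#' @param C Positive clipping threshold.
#' @return Clipped matrix; every row has L2 norm `<= C`.
#' @export
clip_rows <- function(grads, C) {
  if (C <= 0) stopf("C must be positive")
  if (is.null(dim(grads))) grads <- matrix(grads, nrow = 1L)
  bad <- which(!apply(grads, 1L, function(r) all(is.finite(r))))
  if (length(bad)) stopf("non-finite gradient at example %d", bad[1L])
  norms <- sqrt(rowSums(grads^2))
  scale <- 1 / pmax(1, norms / C)
  grads * scale
}

#' Noised mean of clipped per-example gradients
#'
#' Returns `(1/B) * (sum_i row_i + z)` with `z ~ Normal(0, sigma^2 C^2 I)`,
#' exactly the privatized stochastic gradient of DP-SGD. Noise is drawn from
#' the R RNG stream, so the result is deterministic under a fixed seed.
#'
#' @param clipped Matrix `[B, P]` whose rows are already clipped to `C`.
#' @param C Clipping threshold used (sets the noise scale).
#' @param sigma Noise multiplier (>= 0; 0 yields the exact clipped mean).
#' @return Flat privatized mean-gradient vector of length `P`.
#' @export
privatize_mean <- function(clipped, C, sigma) {
  if (sigma < 0) stopf("sigma must be nonnegative")
  if (is.null(dim(clipped))) clipped <- matrix(clipped, nrow = 1L)
  B <- nrow(clipped)
  s <- colSums(clipped)
  if (sigma > 0) s <- s + stats::rnorm(length(s), sd = sigma * C)
  s / B
}

#' One DP-SGD/DP-Adam step on a proxy model
#'
#' Composes [mixed_per_example_grads()] (KL weight `w$beta`, peer detached),
#' [clip_rows()], [privatize_mean()] and [apply_update()], and emits exactly
#' one step receipt for the privacy accountant. Only models trained through
#' this function spend privacy budget.
#'
#' @param model Proxy classifier to update.
#' @param peer Private peer providing distillation targets (`NULL` allowed
#'   when `w$beta = 0`, i.e. plain DP cross-entropy training).
#' @param batch A `pfl_batch`, drawn by Poisson sampling at rate `q`.
#' @param w A [mutual_weights()] object; `beta` is used.
#' @param dp A [dp_config()]; must be enabled.
#' @param opt Optimizer bundle (`rule`, `lr`, `weight_decay`, `state`).
#' @param q Poisson sampling rate that produced the batch, recorded in the
#'   receipt for accounting.
#' @return `list(model, opt, receipt)` where `receipt` has fields
#'   `q`, `sigma`, `steps = 1`.
#' @export
dp_step <- function(model, peer, batch, w, dp, opt, q) {
  if (!isTRUE(dp$enabled))
    stopf("dp_step called with DP disabled; private models must not pass through the DP pipeline")
  grads <- mixed_per_example_grads(model, peer, batch, w$beta)
  gbar <- privatize_mean(clip_rows(grads, dp$clip_C), dp$clip_C, dp$sigma)
  stepped <- opt_step(model, gbar, opt)
  list(model = stepped$model, opt = stepped$opt,
       receipt = list(q = q, sigma = dp$sigma, steps = 1L))
}

#' Poisson-subsample a mini-batch
#'
#' Each example is included independently with probability `q` (sampling
#' "with replacement" across steps in the DP-SGD sense), which is the
#' sampling scheme the subsampled-Gaussian privacy analysis assumes. The
#' expected batch size is `q * N`; empty draws return `NULL` and callers
#' skip the step (no update, no receipt).
#'
#' @param dataset A `pfl_dataset` (see [make_synthetic()]).
#' @param q Sampling rate in (0, 1].
#' @return A `pfl_batch`, or `NULL` if no example was selected.
#' @export
poisson_sample <- function(dataset, q) {
  if (q <= 0 || q > 1) stopf("sampling rate q must lie in (0, 1], got %s",
                             format(q))
  N <- nrow(dataset$x)
  keep <- if (q == 1) rep(TRUE, N) else stats::runif(N) < q
  if (!any(keep)) return(NULL)
  make_batch(dataset$x[keep, , drop = FALSE], dataset$y[keep],
             dataset$n_classes)
}

#' Write / read DP step receipts as JSON lines
#'
#' Each line records `q`, `sigma` and the step count of one privatized
#' gradient release; a ledger file can be replayed into an accountant with
#' [accountant_from_receipts()].
#'
#' @param receipts List of receipts from [dp_step()].
#' @param path Ledger file path.
#' @return `write_receipts` returns `path` invisibly; `read_receipts`
#'   returns the list of receipts.
#' @export
write_receipts <- function(receipts, path) {
  lines <- vapply(receipts, function(r) {
    jsonlite::toJSON(r[c("q", "sigma", "steps")], auto_unbox = TRUE,
                     digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_receipts
#' @export
read_receipts <- function(path) {
  lapply(readLines(path), function(l) jsonlite::fromJSON(l))
}
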