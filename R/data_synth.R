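# Synthetic classification data with the statistical structure of the
# multi-client experiments: Gaussian class blobs, label-skew and Dirichlet
# partitioners, and evaluation metrics.

#' Generate a synthetic Gaussian-blob classification dataset
#'
#' Class `c` is an isotropic Gaussian around a seeded random mean; the
#' means are scaled so that the typical pairwise mean distance is about
#' `sqrt(2) * class_separation` regardless of dimension. Classes are
#' balanced and the generator is a pure function of `seed`.
#' `class_separation = 0` makes classes indistinguishable (chance-level
#' Bayes accuracy); large separation with small `noise_sd` is linearly
#' separable.
#'
#' @param n_classes Number of classes (>= 2).
#' @param dim Feature dimension, or an image shape such as `c(8, 8, 1)`.
#' @param n_per_class Examples per class.
#' @param class_separation Scale of between-class mean distances.
#' @param noise_sd Within-class standard deviation.
#' @param seed Integer seed.
#' @return A `pfl_dataset`: list with `x` (matrix `[N, prod(dim)]`), `y`
#'   (0-based integer labels), `n_classes`, `input_shape`.
#' @export
make_synthetic <- function(n_classes, dim, n_per_class,
                           class_separation = 3, noise_sd = 1, seed = 1) {
  if (n_classes < 2) stopf("n_classes must be >= 2")
  shape <- as.integer(dim)
  if (any(shape <= 0)) stopf("dim entries must be positive")
  D <- prod(shape)
  if (n_per_class < 1) stopf("n_per_class must be >= 1")
  with_seed(as.integer(seed), {
    means <- matrix(stats::rnorm(n_classes * D), n_classes, D) *
      class_separation / sqrt(D)
    y <- rep(0:(n_classes - 1L), each = n_per_class)
    N <- length(y)
    x <- means[y + 1L, , drop = FALSE] +
      matrix(stats::rnorm(N * D, sd = noise_sd), N, D)
    ord <- sample.int(N)
    structure(list(x = x[ord, , drop = FALSE], y = y[ord],
                   n_classes = as.integer(n_classes), input_shape = shape),
              class = "pfl_dataset")
  })
}

#' Subset a dataset by example indices
#' @param dataset A `pfl_dataset`.
#' @param idx Integer indices (1-based).
#' @return The subsetted `pfl_dataset`.
#' @export
subset_dataset <- function(dataset, idx) {
  structure(list(x = dataset$x[idx, , drop = FALSE], y = dataset$y[idx],
                 n_classes = dataset$n_classes,
                 input_shape = dataset$input_shape),
            class = "pfl_dataset")
}

#' @export
print.pfl_dataset <- function(x, ...) {
  cat(sprintf("<pfl_dataset> %d examples, %d classes, input %s\n",
              nrow(x$x), x$n_classes, paste(x$input_shape, collapse = "x")))
  invisible(x)
}

#' Label-skewed client partition
#'
#' Each client is assigned a major class (chosen at random, without
#' replacement while classes remain); `floor(p_major * per_client_n)` of
#' its examples are drawn from that class without replacement, and the
#' remainder uniformly from the pool of all other classes. Client index
#' sets are disjoint. `p_major = 1/n_classes` recovers (approximately) the
#' IID setting; `p_major = 1` gives single-class clients.
#'
#' @param dataset A `pfl_dataset`.
#' @param K Number of clients.
#' @param p_major Fraction of each client's data from its major class, in
#'   `[1/n_classes, 1]`.
#' @param per_client_n Examples per client.
#' @param seed Integer seed.
#' @return A `pfl_partition`: list with `assignments` (list of disjoint
#'   1-based index vectors) and `major_class` (0-based class per client).
#' @export
partition_skewed <- function(dataset, K, p_major, per_client_n, seed = 1) {
  nc <- dataset$n_classes
  if (p_major < 1 / nc - 1e-12 || p_major > 1)
    stopf("p_major must lie in [1/n_classes, 1]")
  with_seed(as.integer(seed), {
    majors <- if (K <= nc) sample.int(nc, K) - 1L else
      sample.int(nc, K, replace = TRUE) - 1L
    pool_by_class <- split(seq_along(dataset$y), dataset$y)
    # randomize within-class order so draws are uniform
    pool_by_class <- lapply(pool_by_class, shuffle)
    n_major <- floor(p_major * per_client_n)
    assignments <- vector("list", K)
    for (k in seq_len(K)) {
      key <- as.character(majors[k])
      if (length(pool_by_class[[key]]) < n_major)
        stopf("insufficient examples of class %s for client %d (need %d, have %d)",
              key, k, n_major, length(pool_by_class[[key]]))
      take <- pool_by_class[[key]][seq_len(n_major)]
      pool_by_class[[key]] <- pool_by_class[[key]][-seq_len(n_major)]
      n_minor <- per_client_n - n_major
      minor_pool <- unlist(pool_by_class[names(pool_by_class) != key],
                           use.names = FALSE)
      if (length(minor_pool) < n_minor)
        stopf("insufficient minor-class examples for client %d", k)
      minor <- draw(minor_pool, n_minor)
      # remove drawn minors from their class pools
      for (key2 in names(pool_by_class)) {
        pool_by_class[[key2]] <- setdiff(pool_by_class[[key2]], minor)
      }
      assignments[[k]] <- c(take, minor)
    }
    structure(list(assignments = assignments, major_class = majors),
              class = "pfl_partition")
  })
}

#' Dirichlet-allocated client partition
#'
#' For each class, its examples are split across the `K` clients with
#' proportions drawn from `Dirichlet(concentration * 1_K)`; counts are
#' realized by largest-remainder rounding so per-class totals are conserved
#' exactly and assignments stay disjoint. Small concentrations give highly
#' skewed label distributions; large concentrations approach uniform.
#'
#' @param dataset A `pfl_dataset`.
#' @param K Number of clients.
#' @param concentration Positive Dirichlet concentration.
#' @param seed Integer seed.
#' @return A `pfl_partition` (no `major_class`).
#' @export
partition_dirichlet <- function(dataset, K, concentration, seed = 1) {
  if (concentration <= 0) stopf("concentration must be positive")
  with_seed(as.integer(seed), {
    assignments <- replicate(K, integer(0), simplify = FALSE)
    for (cls in 0:(dataset$n_classes - 1L)) {
      idx <- shuffle(which(dataset$y == cls))
      g <- stats::rgamma(K, shape = concentration, rate = 1)
      if (all(g == 0)) g <- rep(1, K)  # guard against gamma underflow
      props <- g / sum(g)
      n <- length(idx)
      base <- floor(props * n)
      rem <- n - sum(base)
      if (rem > 0) {
        extra <- order(props * n - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
      }
      cuts <- c(0L, cumsum(base))
      for (k in seq_len(K)) {
        if (base[k] > 0)
          assignments[[k]] <- c(assignments[[k]],
                                idx[(cuts[k] + 1L):cuts[k + 1L]])
      }
    }
    structure(list(assignments = assignments, major_class = NULL),
              class = "pfl_partition")
  })
}

#' Accuracy and macro-averaged accuracy of a classifier
#'
#' Macro-averaged accuracy is the unweighted mean of per-class recalls;
#' classes absent from the test set are excluded from the macro mean.
#'
#' @param model A `pfl_classifier`.
#' @param test_set A `pfl_dataset`.
#' @return Named numeric vector `c(accuracy = ..., macro_accuracy = ...)`.
#' @export
evaluate <- function(model, test_set) {
  if (nrow(test_set$x) == 0L) stopf("test set is empty")
  probs <- forward_probs(model, test_set$x)
  pred <- max.col(probs, ties.method = "first") - 1L
  acc <- mean(pred == test_set$y)
  recalls <- vapply(sort(unique(test_set$y)), function(cls) {
    mean(pred[test_set$y == cls] == cls)
  }, numeric(1))
  c(accuracy = acc, macro_accuracy = mean(recalls))
}
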