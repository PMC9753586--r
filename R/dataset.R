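#' Weighted trajectory dataset
#'
#' The training set for reweighted manifold learning: K samples of n
#' configuration variables augmented with per-sample bias energies and the
#' statistical weights that restore equilibrium averages. For an unbiased
#' trajectory all weights are exactly 1.
#'
#' @param samples K x n numeric matrix of configuration variables (a vector is
#'   treated as K x 1).
#' @param weights K strictly positive statistical weights (default all 1).
#' @param bias_values K bias energies \eqn{V(z_k)} (default all 0).
#' @param times K time stamps (default `seq_len(K)`).
#' @param cv_values K x d' matrix of the biased CVs (default: `samples`).
#' @param metadata named list of provenance (potential, bias state, seed, ...).
#' @return An object of class `trajectory_dataset`.
#' @export
trajectory_dataset <- function(samples, weights = NULL, bias_values = NULL,
                               times = NULL, cv_values = NULL,
                               metadata = list()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  k <- nrow(samples)
  if (k < 1L) stop("dataset needs at least one sample")
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (is.null(weights)) weights <- rep(1, k)
  if (is.null(bias_values)) bias_values <- rep(0, k)
  if (is.null(times)) times <- as.numeric(seq_len(k))
  if (is.null(cv_values)) cv_values <- samples
  cv_values <- as.matrix(cv_values)
  if (length(weights) != k || length(bias_values) != k || length(times) != k ||
      nrow(cv_values) != k)
    stop("weights, bias_values, times and cv_values must all have length K")
  if (!all(is.finite(weights)) || any(weights <= 0))
    stop("weights must be strictly positive and finite")
  structure(list(samples = samples, weights = as.numeric(weights),
                 bias_values = as.numeric(bias_values),
                 times = as.numeric(times), cv_values = cv_values,
                 metadata = metadata),
            class = "trajectory_dataset")
}

#' Number of samples in a dataset
#' @param dataset a [trajectory_dataset()].
#' @return Integer K.
#' @export
n_samples <- function(dataset) nrow(dataset$samples)

#' Subset a trajectory dataset by sample index
#' @param dataset a [trajectory_dataset()].
#' @param idx integer sample indices to keep.
#' @return A `trajectory_dataset` restricted to `idx`.
#' @export
subset_dataset <- function(dataset, idx) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  trajectory_dataset(dataset$samples[idx, , drop = FALSE],
                     weights = dataset$weights[idx],
                     bias_values = dataset$bias_values[idx],
                     times = dataset$times[idx],
                     cv_values = dataset$cv_values[idx, , drop = FALSE],
                     metadata = dataset$metadata)
}

#' @export
print.trajectory_dataset <- function(x, ...) {
  cat("Trajectory dataset: K =", nrow(x$samples), "samples, n =",
      ncol(x$samples), "configuration variables\n")
  w <- range(x$weights)
  cat("  weight range: [", signif(w[1], 4), ",", signif(w[2], 4), "]\n")
  invisible(x)
}

#' @export
as.data.frame.trajectory_dataset <- function(x, ...) {
  d <- as.data.frame(x$samples)
  names(d) <- paste0("x", seq_len(ncol(x$samples)))
  d$time <- x$times
  d$bias <- x$bias_values
  d$weight <- x$weights
  d
}
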