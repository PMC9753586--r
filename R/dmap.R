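#' Spectral decomposition of a Markov model into a diffusion embedding
#'
#' Computes the top eigenpairs of a row-stochastic Markov transition matrix
#' via the symmetric conjugate \eqn{S = D^{1/2} M D^{-1/2}} with
#' \eqn{D = \mathrm{diag}(\pi)}, where \eqn{\pi} is the stationary
#' distribution (exact for a [build_markov_model()] result, estimated by
#' power iteration for a plain matrix). This route guarantees a real
#' spectrum, \eqn{\lambda_0 = 1} with a constant right eigenvector, and
#' recovers the stationary density as the left eigenvector at
#' \eqn{\lambda = 1}.
#'
#' Right eigenvectors are normalized so that
#' \eqn{\sum_k \pi_k \psi_l(x_k)^2 = 1} (hence \eqn{\psi_0 \equiv 1}) and
#' signed so the largest-magnitude entry is positive.
#'
#' Note on the density coordinate: for a row-stochastic matrix the right
#' eigenvector at \eqn{\lambda_0 = 1} is constant, so the equilibrium
#' density is carried by the *left* eigenvector, exposed as
#' `left_eigenvector_0` (and as the zeroth column of the coordinates when
#' `density_coordinate = TRUE`).
#'
#' @param model a `markov_model` or a row-stochastic matrix.
#' @param m number of eigenpairs to keep (default 10, capped at K).
#' @param lag_time time separation represented by one Markov step (default:
#'   the dataset's sampling interval when available, else 1).
#' @param tol tolerance for the stochasticity and symmetry checks.
#' @return An object of class `diffusion_embedding` with `eigenvalues`
#'   (non-increasing, \eqn{\lambda_0 = 1}), `right_eigenvectors` (K x m),
#'   `left_eigenvector_0` (the stationary density, sums to 1),
#'   `coordinates` (K x m, column l is \eqn{\lambda_l \psi_l}),
#'   `spectral_gap_index`, `gap_ratio` and `lag_time`.
#' @export
spectral_decomposition <- function(model, m = 10, lag_time = NULL,
                                   tol = 1e-8) {
  if (inherits(model, "markov_model")) {
    tm <- model$transition_matrix
    pi0 <- model$stationary
    if (is.null(lag_time) && !is.null(model$dataset$times) &&
        length(model$dataset$times) > 1)
      lag_time <- stats::median(diff(model$dataset$times))
  } else {
    tm <- as.matrix(model)
    pi0 <- NULL
  }
  if (is.null(lag_time)) lag_time <- 1
  k <- nrow(tm)
  if (ncol(tm) != k) stop("transition matrix must be square")
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-8))
    stop("input is not row-stochastic")
  m <- min(m, k)
  if (is.null(pi0)) pi0 <- .power_iteration(tm)
  s <- sqrt(pi0)
  smat <- (tm * outer(s, 1 / s))
  asym <- max(abs(smat - t(smat))) / max(abs(smat))
  if (asym > 1e-6)
    stop("conjugated matrix is not symmetric (relative asymmetry ",
         signif(asym, 3), "); the reweighting factor may be inconsistent")
  smat <- (smat + t(smat)) / 2
  ed <- eigen(smat, symmetric = TRUE)
  ord <- order(ed$values, decreasing = TRUE)[seq_len(m)]
  lambda <- ed$values[ord]
  v <- ed$vectors[, ord, drop = FALSE]
  right <- v / s
  # normalize: sum_k pi_k psi^2 = 1, largest-magnitude entry positive
  for (j in seq_len(m)) {
    nrm <- sqrt(sum(pi0 * right[, j]^2))
    right[, j] <- right[, j] / nrm
    if (right[which.max(abs(right[, j])), j] < 0)
      right[, j] <- -right[, j]
  }
  if (abs(lambda[1] - 1) > tol)
    warning("leading eigenvalue deviates from 1 by ",
            signif(abs(lambda[1] - 1), 3))
  coords <- sweep(right, 2, lambda, "*")
  gap <- if (m >= 3) spectral_gap(lambda) else
    list(index = NA_integer_, ratio = NA_real_)
  structure(list(eigenvalues = lambda, right_eigenvectors = right,
                 left_eigenvector_0 = pi0 / sum(pi0),
                 coordinates = coords, spectral_gap_index = gap$index,
                 gap_ratio = gap$ratio, lag_time = lag_time),
            class = "diffusion_embedding")
}

.power_iteration <- function(tm, max_iter = 10000, tol = 1e-14) {
  k <- nrow(tm)
  p <- rep(1 / k, k)
  for (i in seq_len(max_iter)) {
    p_new <- drop(crossprod(tm, p))
    p_new <- p_new / sum(p_new)
    if (max(abs(p_new - p)) < tol) return(p_new)
    p <- p_new
  }
  p
}

#' Diffusion coordinates
#'
#' Column \eqn{l} of the diffusion map is \eqn{\lambda_l \psi_l(x_k)}; the
#' truncation to the first \eqn{d} columns is justified by the spectral gap.
#' Because the right eigenvector at \eqn{\lambda_0 = 1} is constant for a
#' row-stochastic matrix, `density_coordinate = TRUE` (default) replaces the
#' zeroth column by the stationary density \eqn{\pi} so the first coordinate
#' carries the equilibrium-density information, as in density-vs-coordinate
#' diffusion-map plots.
#'
#' @param embedding a [spectral_decomposition()] result.
#' @param d number of coordinates.
#' @param density_coordinate expose the stationary density as coordinate 0.
#' @return K x d matrix of diffusion coordinates.
#' @export
diffusion_coordinates <- function(embedding, d,
                                  density_coordinate = FALSE) {
  stopifnot(inherits(embedding, "diffusion_embedding"))
  if (d > ncol(embedding$coordinates))
    stop("d exceeds the number of computed eigenpairs")
  out <- embedding$coordinates[, seq_len(d), drop = FALSE]
  if (density_coordinate && d >= 1)
    out[, 1] <- embedding$eigenvalues[1] * embedding$left_eigenvector_0
  out
}

#' Effective timescales from eigenvalues
#'
#' \eqn{t_l = -\tau / \ln \lambda_l}, with \eqn{\tau} the lag time of the
#' Markov chain. \eqn{\lambda = 1} (within `tol`, to absorb eigensolver
#' rounding of the stationary eigenvalue) maps to \eqn{+\infty}; non-positive
#' eigenvalues carry no timescale and are reported as 0 with a warning.
#'
#' @param eigenvalues numeric vector of eigenvalues.
#' @param lag_time lag time \eqn{\tau} in the trajectory's time units.
#' @param tol eigenvalues within `tol` of 1 are treated as exactly 1.
#' @return Timescales, same length as `eigenvalues`.
#' @export
effective_timescales <- function(eigenvalues, lag_time = 1, tol = 1e-12) {
  stopifnot(lag_time > 0)
  t_l <- rep(NA_real_, length(eigenvalues))
  pos <- eigenvalues > 0 & eigenvalues < 1 - tol
  t_l[eigenvalues >= 1 - tol] <- Inf
  t_l[pos] <- -lag_time / log(eigenvalues[pos])
  if (any(eigenvalues <= 0)) {
    warning("non-positive eigenvalues reported as timescale 0")
    t_l[eigenvalues <= 0] <- 0
  }
  t_l
}

#' Spectral gap of a sorted eigenvalue sequence
#'
#' Finds the truncation dimension \eqn{d} maximizing the drop
#' \eqn{\lambda_{d-1} - \lambda_d} (over \eqn{d \ge 1}) and reports the
#' ratio \eqn{\lambda_d / \lambda_{d-1}}, the order of the truncation error
#' incurred by keeping only the first \eqn{d} coordinates.
#'
#' @param eigenvalues eigenvalues sorted non-increasing, at least 3.
#' @return A list with `index` (the number of retained eigenpairs \eqn{d})
#'   and `ratio` (the truncation-error estimate).
#' @export
spectral_gap <- function(eigenvalues) {
  if (length(eigenvalues) < 3) stop("need at least 3 eigenvalues")
  drops <- -diff(eigenvalues)
  d <- which.max(drops)
  list(index = d, ratio = eigenvalues[d + 1] / eigenvalues[d])
}

#' @export
print.diffusion_embedding <- function(x, ...) {
  cat("Diffusion embedding: K =", nrow(x$coordinates), "samples,",
      length(x$eigenvalues), "eigenpairs\n")
  cat("  eigenvalues:", paste(signif(utils::head(x$eigenvalues, 6), 4),
                              collapse = ", "),
      if (length(x$eigenvalues) > 6) "...", "\n")
  if (!is.na(x$spectral_gap_index))
    cat("  spectral gap after index", x$spectral_gap_index - 1,
        "(truncation-error ratio", signif(x$gap_ratio, 3), ")\n")
  invisible(x)
}
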