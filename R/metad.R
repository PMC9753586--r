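#' Well-tempered metadynamics bias state
#'
#' Holds the accumulated history-dependent bias: the deposited Gaussian hills
#' (centers, widths, heights), the bias factor \eqn{\gamma}, and bookkeeping
#' needed to continue deposition. The bias potential is
#' \deqn{V(z) = \sum_l h_l \exp\{-(z - z_l)^2 / (2 \sigma_l^2)\},}
#' with hill heights scaled down by the already-accumulated bias so that the
#' biased distribution converges to \eqn{[P(z)]^{1/\gamma}}.
#'
#' @param hill_centers,hill_widths,hill_heights numeric vectors describing the
#'   deposited hills (may be empty).
#' @param bias_factor bias factor \eqn{\gamma > 1}; `Inf` gives standard
#'   (non-tempered) metadynamics.
#' @param initial_height height of a hill deposited on zero prior bias
#'   (\eqn{k_B T}).
#' @param hill_width default width \eqn{\sigma} for newly deposited hills.
#' @param deposition_stride integrator steps between depositions.
#' @param c_value the time-dependent normalization constant \eqn{c}; 0 for an
#'   empty bias, otherwise set by [compute_c()].
#' @return An object of class `bias_state`.
#' @export
bias_state <- function(hill_centers = numeric(), hill_widths = numeric(),
                       hill_heights = numeric(), bias_factor = 10,
                       initial_height = 1.2, hill_width = 0.2,
                       deposition_stride = 500L, c_value = 0) {
  if (!(bias_factor > 1)) stop("bias_factor must be > 1 (Inf allowed)")
  stopifnot(length(hill_centers) == length(hill_heights),
            length(hill_centers) == length(hill_widths))
  if (length(hill_heights) && any(hill_heights <= 0))
    stop("all hill heights must be positive")
  structure(list(hill_centers = as.numeric(hill_centers),
                 hill_widths = as.numeric(hill_widths),
                 hill_heights = as.numeric(hill_heights),
                 bias_factor = bias_factor, initial_height = initial_height,
                 hill_width = hill_width,
                 deposition_stride = as.integer(deposition_stride),
                 c_value = c_value),
            class = "bias_state")
}

#' Deposit one well-tempered hill
#'
#' Appends a Gaussian hill at the current CV value `z` with height
#' \deqn{h = h_0 \exp\{-V(z) / [(\gamma - 1) k_B T]\},}
#' where \eqn{V(z)} is the bias accumulated before this deposition. Heights
#' therefore shrink when the walker revisits already-biased regions; for
#' \eqn{\gamma \to \infty} every hill keeps the initial height.
#'
#' @param bias a [bias_state()].
#' @param z CV value at which to center the hill.
#' @param beta inverse thermal energy \eqn{1/k_B T} (default 1).
#' @return The updated `bias_state` (note: `c_value` is not refreshed; call
#'   [compute_c()] when weights are needed).
#' @export
deposit_hill <- function(bias, z, beta = 1) {
  stopifnot(inherits(bias, "bias_state"), is.finite(z), beta > 0)
  v <- evaluate_bias(bias, z)
  h <- if (is.finite(bias$bias_factor)) {
    bias$initial_height * exp(-v * beta / (bias$bias_factor - 1))
  } else {
    bias$initial_height
  }
  bias$hill_centers <- c(bias$hill_centers, z)
  bias$hill_widths <- c(bias$hill_widths, bias$hill_width)
  bias$hill_heights <- c(bias$hill_heights, h)
  bias
}

#' Evaluate the metadynamics bias potential
#'
#' @param bias a [bias_state()].
#' @param z CV values (vectorized).
#' @return \eqn{V(z)} in \eqn{k_B T}; 0 everywhere for an empty bias.
#' @export
evaluate_bias <- function(bias, z) {
  stopifnot(inherits(bias, "bias_state"), is.numeric(z))
  v <- numeric(length(z))
  n <- length(bias$hill_centers)
  if (n == 0L) return(v)
  # chunk over hills to keep the K x n_hills intermediate bounded
  chunk <- max(1L, floor(2e6 / max(1L, length(z))))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    d <- outer(z, bias$hill_centers[idx], "-")
    v <- v + drop(exp(-sweep(d^2, 2, 2 * bias$hill_widths[idx]^2, "/")) %*%
                    bias$hill_heights[idx])
  }
  v
}

#' Time-dependent constant c of a well-tempered bias
#'
#' Estimates the normalization constant appearing in the statistical weights
#' \eqn{w = e^{\beta(V - c)}} from the bias evaluated on a CV grid:
#' \deqn{c = \frac{1}{\beta} \ln
#'   \frac{\sum_{\rm grid} e^{\beta \gamma V / (\gamma - 1)}}
#'        {\sum_{\rm grid} e^{\beta V / (\gamma - 1)}}.}
#' The grid must cover the CV range actually sampled. Computed with
#' log-sum-exp shifts so biases of hundreds of \eqn{k_B T} are safe.
#'
#' @param bias a [bias_state()], or a numeric vector of bias values already
#'   evaluated on the grid (then `bias_factor` must be given).
#' @param grid CV grid points (required when `bias` is a `bias_state`).
#' @param beta inverse thermal energy (default 1).
#' @param bias_factor \eqn{\gamma}, only used when `bias` is numeric.
#' @return The constant \eqn{c} in energy units; 0 for an empty bias.
#' @export
compute_c <- function(bias, grid = NULL, beta = 1, bias_factor = NULL) {
  stopifnot(beta > 0)
  if (inherits(bias, "bias_state")) {
    if (length(bias$hill_centers) == 0L) return(0)
    if (is.null(grid) || length(grid) == 0L)
      stop("compute_c needs a CV grid covering the sampled range")
    v <- evaluate_bias(bias, grid)
    gamma <- bias$bias_factor
  } else {
    v <- as.numeric(bias)
    if (length(v) == 0L) stop("empty bias-value grid")
    if (is.null(bias_factor)) stop("bias_factor required for numeric input")
    gamma <- bias_factor
  }
  if (is.finite(gamma)) {
    a <- beta * gamma * v / (gamma - 1)
    b <- beta * v / (gamma - 1)
  } else {
    a <- beta * v
    b <- rep(0, length(v))
  }
  (logsumexp(a) - logsumexp(b)) / beta
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Statistical weights from relative bias
#'
#' \deqn{w_k = e^{\beta (V_k - c)},} the importance correction that restores
#' equilibrium averages from samples drawn under the bias. An unbiased run
#' (\eqn{V \equiv 0}, \eqn{c = 0}) gives unit weights exactly. If the relative
#' bias is large enough to overflow doubles, the whole set is shifted by a
#' common factor (weights are only ever used up to a constant) and a warning
#' reports the shift.
#'
#' @param bias_values per-sample bias energies \eqn{V_k}.
#' @param c_value the constant from [compute_c()].
#' @param beta inverse thermal energy (default 1).
#' @return Strictly positive weights, same length as `bias_values`.
#' @export
compute_weights <- function(bias_values, c_value, beta = 1) {
  stopifnot(is.numeric(bias_values), all(is.finite(bias_values)),
            is.finite(c_value), beta > 0)
  lw <- beta * (bias_values - c_value)
  if (max(lw) > 700) {
    shift <- max(lw) - 700
    warning("weights rescaled by exp(-", signif(shift, 4),
            ") to avoid overflow")
    lw <- lw - shift
  }
  exp(lw)
}

#' @export
print.bias_state <- function(x, ...) {
  cat("Well-tempered metadynamics bias:", length(x$hill_centers), "hills,",
      "gamma =", x$bias_factor, "\n")
  if (length(x$hill_centers))
    cat("  height range:", signif(min(x$hill_heights), 4), "-",
        signif(max(x$hill_heights), 4), " c =", signif(x$c_value, 5), "\n")
  invisible(x)
}
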