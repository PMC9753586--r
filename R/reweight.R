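#' Kernel and reweighting specification
#'
#' Settings for building a Markov transition matrix from weighted samples.
#' The Gaussian kernel convention used throughout the package is
#' \deqn{G_\varepsilon(x_k, x_l) = \exp\{-\|x_k - x_l\|^2 / (2\varepsilon)\}.}
#'
#' Reweighting modes:
#' \describe{
#'   \item{`none`}{plain (anisotropic) diffusion-map kernel; with
#'     `alpha = 0` this is the classical normalized graph Laplacian
#'     construction.}
#'   \item{`diffusion`}{diffusion reweighting
#'     \eqn{r_{kl} = w_l / \sqrt{w_k \rho_V(x_k)\, w_l \rho_V(x_l)}} at
#'     \eqn{\alpha = 1/2}, with \eqn{\rho_V} the biased kernel density; for
#'     other \eqn{\alpha} the general form
#'     \eqn{r_{kl} = w_l / (\rho_k \rho_l)^\alpha} with the weighted
#'     (unbiased) density is used.}
#'   \item{`geometric_mean`}{\eqn{r_{kl} = \sqrt{w_k w_l}} (the mrse
#'     reweighting).}
#'   \item{`density`}{\eqn{r_{kl} = \sqrt{\rho_k \rho_l}} with the weighted
#'     density (the stke reweighting).}
#' }
#'
#' @param epsilon kernel scale \eqn{\varepsilon > 0}; `NULL` (default) uses
#'   the median of the off-diagonal pairwise distances.
#' @param alpha anisotropic diffusion parameter in \[0, 1\] (default 1/2, the
#'   value that asymptotically models the slowest degrees of freedom).
#' @param reweighting one of `"diffusion"`, `"none"`, `"geometric_mean"`,
#'   `"density"`.
#' @param density_floor densities are clipped below at this value before
#'   exponentiation (default 1e-300).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(epsilon = NULL, alpha = 0.5,
                        reweighting = c("diffusion", "none", "geometric_mean",
                                        "density"),
                        density_floor = 1e-300) {
  reweighting <- match.arg(reweighting)
  if (!is.null(epsilon) && epsilon <= 0) stop("epsilon must be positive")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (density_floor <= 0) stop("density_floor must be positive")
  structure(list(epsilon = epsilon, alpha = alpha, reweighting = reweighting,
                 density_floor = density_floor),
            class = "kernel_spec")
}

#' Pairwise squared Euclidean distances
#'
#' @param samples K x n matrix (a vector is treated as K x 1).
#' @return Symmetric K x K matrix of squared distances with zero diagonal.
#' @export
pairwise_sq_distances <- function(samples) {
  x <- as.matrix(samples)
  if (!all(is.finite(x))) stop("samples must be finite")
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  (d2 + t(d2)) / 2
}

#' Gaussian kernel matrix
#'
#' \eqn{G_{kl} = \exp\{-d^2_{kl} / (2\varepsilon)\}}; unit diagonal,
#' symmetric.
#'
#' @param sq_distances K x K squared-distance matrix.
#' @param epsilon positive kernel scale.
#' @return K x K kernel matrix.
#' @export
gaussian_kernel <- function(sq_distances, epsilon) {
  if (epsilon <= 0) stop("epsilon must be positive")
  exp(-sq_distances / (2 * epsilon))
}

#' Median-distance heuristic for the kernel scale
#'
#' Returns the median of the off-diagonal pairwise (not squared) distances,
#' the standard data-driven choice for \eqn{\varepsilon}.
#'
#' @param sq_distances K x K squared-distance matrix, K >= 2.
#' @return A single positive number.
#' @export
epsilon_from_median <- function(sq_distances) {
  k <- nrow(sq_distances)
  if (is.null(k) || k < 2) stop("need at least two samples")
  stats::median(sqrt(sq_distances[upper.tri(sq_distances)]))
}

#' Biased kernel density estimate
#'
#' \eqn{\rho_V(x_k) = \sum_l G_\varepsilon(x_k, x_l)}: the sample density as
#' seen under the bias potential (every sample counts equally).
#'
#' @param kernel_matrix K x K Gaussian kernel matrix.
#' @return K positive densities.
#' @export
biased_density <- function(kernel_matrix) {
  rowSums(kernel_matrix)
}

#' Weighted (unbiased) kernel density estimate
#'
#' \eqn{\rho(x_k) = \sum_l w_l\, G_\varepsilon(x_k, x_l)}: reweighting each
#' kernel term recovers the equilibrium density up to a multiplicative
#' constant. With unit weights this equals [biased_density()] exactly.
#'
#' @param kernel_matrix K x K Gaussian kernel matrix.
#' @param weights K strictly positive statistical weights.
#' @return K positive densities.
#' @export
weighted_density <- function(kernel_matrix, weights) {
  if (length(weights) != nrow(kernel_matrix))
    stop("weights must have one entry per sample")
  if (any(weights <= 0) || !all(is.finite(weights)))
    stop("weights must be strictly positive and finite")
  drop(kernel_matrix %*% weights)
}

#' Anisotropic diffusion kernel
#'
#' \eqn{A_{kl} = G_{kl} / (\rho_k^\alpha \rho_l^\alpha)}. With
#' \eqn{\alpha = 0} the kernel is returned unchanged; \eqn{\alpha = 1}
#' removes the density influence entirely (Laplace-Beltrami limit).
#'
#' @param kernel_matrix K x K Gaussian kernel matrix.
#' @param densities K positive densities.
#' @param alpha anisotropic diffusion parameter in \[0, 1\].
#' @param density_floor densities below this are clipped (with a warning).
#' @return K x K matrix.
#' @export
anisotropic_kernel <- function(kernel_matrix, densities, alpha,
                               density_floor = 1e-300) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (any(densities < density_floor)) {
    warning("densities below the floor were clipped; ",
            "consider a larger epsilon")
    densities <- pmax(densities, density_floor)
  }
  ra <- densities^(-alpha)
  kernel_matrix * outer(ra, ra)
}

#' Diffusion reweighting factor
#'
#' The pairwise factor that unbiases a Markov transition matrix built from
#' biased samples. Two forms are available:
#' \describe{
#'   \item{final form (default)}{at \eqn{\alpha = 1/2}, substituting the
#'     unbiased density by \eqn{\rho \approx w\,\rho_V}:
#'     \deqn{r_{kl} = \frac{w_l}
#'       {\sqrt{w_k \rho_V(x_k)\, w_l \rho_V(x_l)}}.}}
#'   \item{general form}{\eqn{r_{kl} = w_l / (\rho_k^\alpha \rho_l^\alpha)}
#'     with the weighted (unbiased) densities passed via `densities`.}
#' }
#' Any factor depending only on the row index k cancels under the row
#' normalization of the transition matrix, so both forms give identical
#' Markov matrices whenever \eqn{\rho = w\,\rho_V} holds.
#'
#' @param weights K statistical weights.
#' @param biased_densities K biased densities \eqn{\rho_V} (final form).
#' @param alpha anisotropic parameter; the final form requires 1/2.
#' @param densities optional K unbiased densities; if given, the general
#'   form is used and `biased_densities` is ignored.
#' @return K x K reweighting matrix.
#' @export
diffusion_reweighting_factor <- function(weights, biased_densities = NULL,
                                         alpha = 0.5, densities = NULL) {
  k <- length(weights)
  if (!is.null(densities)) {
    if (length(densities) != k) stop("densities must have length K")
    ra <- densities^(-alpha)
    return(outer(ra, weights * ra))
  }
  if (is.null(biased_densities) || length(biased_densities) != k)
    stop("biased_densities must have length K")
  if (!isTRUE(all.equal(alpha, 0.5)))
    stop("the final (biased-density) form is derived for alpha = 1/2; ",
         "pass unbiased `densities` for other alpha")
  s <- sqrt(weights * biased_densities)
  outer(1 / s, weights / s)
}

#' Build a reweighted Markov transition matrix
#'
#' Constructs the row-stochastic matrix
#' \deqn{M_{kl} = \frac{r_{kl} G_{kl}}{\sum_m r_{km} G_{km}}}
#' from a weighted dataset, with the reweighting mode of the [kernel_spec()].
#' All modes used here have reweighting factors of the separable form
#' \eqn{r_{kl} = \phi_k \psi_l}; the row factor \eqn{\phi} cancels under
#' normalization, so internally the matrix is assembled in log space from
#' \eqn{\log G_{kl} + \log \psi_l} with a per-row max shift, which keeps the
#' construction exact for weights spanning hundreds of orders of magnitude.
#' The exact stationary distribution \eqn{\pi_k \propto u_k \psi_k} (with
#' \eqn{u} the unnormalized row sums) is stored with the model, and makes the
#' matrix conjugate to a symmetric one, so its spectrum is real.
#'
#' @param dataset a [trajectory_dataset()], or a K x n sample matrix.
#' @param spec a [kernel_spec()].
#' @param weights optional weights when `dataset` is a plain matrix.
#' @return An object of class `markov_model` with elements
#'   `transition_matrix`, `kernel_matrix`, `reweighting_matrix`, `densities`,
#'   `stationary`, `epsilon`, `psi`, `spec`, `dataset`.
#' @export
build_markov_model <- function(dataset, spec = kernel_spec(),
                               weights = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (!inherits(dataset, "trajectory_dataset"))
    dataset <- trajectory_dataset(dataset, weights = weights)
  x <- dataset$samples
  w <- dataset$weights
  k <- nrow(x)
  if (k < 2) stop("need at least two samples")
  d2 <- pairwise_sq_distances(x)
  eps <- if (is.null(spec$epsilon)) epsilon_from_median(d2) else spec$epsilon
  log_g <- -d2 / (2 * eps)
  g <- exp(log_g)
  rho_v <- biased_density(g)
  dens <- switch(spec$reweighting,
                 none = rho_v,
                 diffusion = rho_v,
                 geometric_mean = rho_v,
                 density = weighted_density(g, w))
  # separable reweighting r_kl = phi_k * psi_l; phi cancels on normalization
  log_psi <- switch(spec$reweighting,
    none = -spec$alpha * log(pmax(rho_v, spec$density_floor)),
    diffusion = {
      if (isTRUE(all.equal(spec$alpha, 0.5))) {
        0.5 * (log(w) - log(pmax(rho_v, spec$density_floor)))
      } else {
        rho <- weighted_density(g, w)
        log(w) - spec$alpha * log(pmax(rho, spec$density_floor))
      }
    },
    geometric_mean = 0.5 * log(w),
    density = 0.5 * log(pmax(weighted_density(g, w), spec$density_floor)))
  off_g <- log_g
  diag(off_g) <- -Inf
  isolated <- apply(off_g, 1, max) < log(1e-300)
  if (any(isolated))
    stop("sample(s) ", paste(which(isolated), collapse = ", "),
         " are isolated: all off-diagonal kernel values underflow; ",
         "increase epsilon")
  log_a <- sweep(log_g, 2, log_psi, "+")
  row_max <- apply(log_a, 1, max)
  a <- exp(log_a - row_max)
  u <- rowSums(a)
  m <- a / u
  # exact stationary distribution: pi_k proportional to u_k * psi_k,
  # with u the *unshifted* row sums, recovered in log space
  log_u <- row_max + log(u)
  log_pi <- log_u + log_psi
  log_pi <- log_pi - logsumexp(log_pi)
  # the reweighting matrix as documented (row factor included), for inspection
  log_phi <- switch(spec$reweighting,
    none = -spec$alpha * log(pmax(rho_v, spec$density_floor)),
    diffusion = if (isTRUE(all.equal(spec$alpha, 0.5)))
      -0.5 * (log(w) + log(pmax(rho_v, spec$density_floor)))
    else -spec$alpha * log(pmax(weighted_density(g, w), spec$density_floor)),
    geometric_mean = 0.5 * log(w),
    density = 0.5 * log(pmax(weighted_density(g, w), spec$density_floor)))
  structure(list(transition_matrix = m, kernel_matrix = g,
                 reweighting_matrix = exp(outer(log_phi, log_psi, "+")),
                 densities = dens, stationary = exp(log_pi),
                 psi = exp(log_psi), epsilon = eps, spec = spec,
                 dataset = dataset),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("Markov model: K =", nrow(x$transition_matrix),
      "| reweighting =", x$spec$reweighting,
      "| alpha =", x$spec$alpha,
      "| epsilon =", signif(x$epsilon, 5), "\n")
  invisible(x)
}
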