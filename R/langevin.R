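#' Langevin integrator configuration
#'
#' Settings for the underdamped Langevin dynamics (BAOAB splitting). Units
#' are natural: energies in \eqn{k_B T} at \eqn{T = 1}, time in the
#' integrator's own units.
#'
#' @param temperature thermal energy \eqn{k_B T} (default 1).
#' @param friction friction coefficient (inverse time, default 10).
#' @param time_step integration step (default 0.005).
#' @param n_steps total number of steps.
#' @param stride record a sample every `stride` steps (default 10).
#' @param seed integer RNG seed controlling the thermostat noise.
#' @return An object of class `langevin_config`.
#' @export
langevin_config <- function(temperature = 1, friction = 10, time_step = 0.005,
                            n_steps = 5e6, stride = 10L, seed = 1L) {
  stopifnot(time_step >= 0, friction >= 0, temperature >= 0, stride >= 1,
            n_steps >= 1)
  structure(list(temperature = temperature, friction = friction,
                 time_step = time_step, n_steps = n_steps,
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "langevin_config")
}

#' Well-tempered metadynamics configuration
#'
#' @param initial_height height of the first hill in \eqn{k_B T}
#'   (default 1.2, a typical choice of order the thermal energy).
#' @param hill_width Gaussian width \eqn{\sigma} of deposited hills (default
#'   0.2, about half the narrowest well width of the packaged potential).
#' @param bias_factor \eqn{\gamma > 1} (default 10).
#' @param deposition_stride steps between hill depositions (default 500).
#' @param n_grid bias grid resolution over the potential domain (default
#'   2048).
#' @return An object of class `metad_config`.
#' @export
metad_config <- function(initial_height = 1.2, hill_width = 0.2,
                         bias_factor = 10, deposition_stride = 500L,
                         n_grid = 2048L) {
  if (!(bias_factor > 1)) stop("bias_factor must be > 1")
  stopifnot(initial_height > 0, hill_width > 0, deposition_stride >= 1,
            n_grid >= 16)
  structure(list(initial_height = initial_height, hill_width = hill_width,
                 bias_factor = bias_factor,
                 deposition_stride = as.integer(deposition_stride),
                 n_grid = as.integer(n_grid)),
            class = "metad_config")
}

#' One BAOAB Langevin step
#'
#' A single update of the BAOAB splitting (half kick, half drift, full
#' Ornstein-Uhlenbeck friction/noise, half drift, half kick). In the
#' deterministic limit (`temperature = 0`, zero force) the velocity contracts
#' by `exp(-friction * time_step)` per step; `time_step = 0` is the identity.
#'
#' @param position,velocity current phase-space point (scalars).
#' @param force either a function `force(x)` returning \eqn{-U'(x)}, or a
#'   single number treated as a constant force over the step.
#' @param config a [langevin_config()] (only `temperature`, `friction`,
#'   `time_step` are used).
#' @return A list with updated `position` and `velocity`.
#' @export
langevin_step <- function(position, velocity, force, config) {
  stopifnot(inherits(config, "langevin_config"),
            is.finite(position), is.finite(velocity))
  f <- if (is.function(force)) force else function(x) force
  f0 <- f(position)
  if (!is.finite(f0)) stop("non-finite force at x = ", position)
  dt <- config$time_step
  c1 <- exp(-config$friction * dt)
  c3 <- sqrt(config$temperature * (1 - c1^2))
  v <- velocity + 0.5 * dt * f0
  x <- position + 0.5 * dt * v
  v <- c1 * v + c3 * stats::rnorm(1)
  x <- x + 0.5 * dt * v
  f1 <- f(x)
  if (!is.finite(f1)) stop("non-finite force at x = ", x)
  v <- v + 0.5 * dt * f1
  list(position = x, velocity = v)
}

#' Run a (biased) Langevin simulation on a model potential
#'
#' Full orchestration of the data-generating experiment: integrate
#' underdamped Langevin dynamics with the BAOAB scheme, optionally depositing
#' well-tempered metadynamics hills on the fly (the biased CV is the particle
#' position), discard an initial transient, and attach statistical weights
#' computed from the final bias under the quasi-stationary assumption (the
#' relative bias \eqn{V - c} no longer changes appreciably once the run is
#' converged). Outside the declared domain a half-harmonic wall restrains the
#' particle; triggered walls are counted in the metadata.
#'
#' The bias is accumulated on a grid (resolution `metad$n_grid`) and
#' interpolated linearly, as grid-based metadynamics codes do; the individual
#' hills are kept so the exact [bias_state()] can be reconstructed and
#' written to a HILLS file.
#'
#' @param potential a [model_potential()].
#' @param config a [langevin_config()].
#' @param metad a [metad_config()] or `NULL` for an unbiased run.
#' @param burn_in fraction of initial samples discarded before weighting
#'   (default 0.2).
#' @param x0,v0 initial position (default: the deepest well center) and
#'   velocity (default: Maxwell-Boltzmann draw).
#' @param wall_k force constant of the half-harmonic domain walls.
#' @return A [trajectory_dataset()] whose metadata records the potential, the
#'   final `bias_state` (with `c_value`), the bias grid, the seed and the
#'   wall-hit count.
#' @export
run_biased_simulation <- function(potential, config, metad = NULL,
                                  burn_in = 0.2, x0 = NULL, v0 = NULL,
                                  wall_k = 1000) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(config, "langevin_config"),
            burn_in >= 0, burn_in < 1)
  if (!is.null(metad)) stopifnot(inherits(metad, "metad_config"))
  set.seed(config$seed)
  if (is.null(x0))
    x0 <- potential$centers[which.max(potential$depths)]
  if (is.null(v0))
    v0 <- sqrt(config$temperature) * stats::rnorm(1)
  use_metad <- !is.null(metad)
  res <- cpp_run_langevin(
    potential$depths, potential$centers, potential$widths,
    potential$domain[1], potential$domain[2], wall_k,
    config$temperature, config$friction, config$time_step, x0, v0,
    as.numeric(config$n_steps), config$stride,
    use_metad,
    if (use_metad) metad$initial_height else 0,
    if (use_metad) metad$hill_width else 1,
    if (use_metad) metad$bias_factor else 10,
    if (use_metad) metad$deposition_stride else 1L,
    if (use_metad) metad$n_grid else 16L)
  if (res$n_wall_hits > 0)
    message("domain wall triggered ", res$n_wall_hits, " times")
  keep <- seq_len(length(res$x))
  n_burn <- floor(burn_in * length(keep))
  if (n_burn > 0) keep <- keep[-seq_len(n_burn)]
  beta <- 1 / config$temperature
  if (use_metad) {
    bias <- bias_state(hill_centers = res$hill_centers,
                       hill_widths = rep(metad$hill_width,
                                         length(res$hill_centers)),
                       hill_heights = res$hill_heights,
                       bias_factor = metad$bias_factor,
                       initial_height = metad$initial_height,
                       hill_width = metad$hill_width,
                       deposition_stride = metad$deposition_stride)
    c_value <- compute_c(res$grid_bias, beta = beta,
                         bias_factor = metad$bias_factor)
    bias$c_value <- c_value
    bias_vals <- res$bias[keep]
    weights <- compute_weights(bias_vals, c_value, beta = beta)
  } else {
    bias <- NULL
    c_value <- 0
    bias_vals <- rep(0, length(keep))
    weights <- rep(1, length(keep))
  }
  trajectory_dataset(
    samples = matrix(res$x[keep], ncol = 1),
    weights = weights, bias_values = bias_vals, times = res$time[keep],
    metadata = list(potential = potential, langevin = config,
                    metad = metad, bias = bias, c_value = c_value,
                    bias_grid = res$grid, grid_bias = res$grid_bias,
                    hill_times = res$hill_times, seed = config$seed,
                    n_wall_hits = res$n_wall_hits, burn_in = burn_in))
}
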