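#' mrse pairwise reweighting factor
#'
#' The geometric mean of the statistical weights,
#' \eqn{r_{kl} = \sqrt{w_k w_l}}; appropriate because the bias potential is
#' additive in the exponent of the weights.
#'
#' @param weights K strictly positive weights.
#' @return Symmetric K x K matrix.
#' @export
mrse_reweighting <- function(weights) {
  if (any(weights <= 0)) stop("weights must be strictly positive")
  s <- sqrt(weights)
  outer(s, s)
}

#' stke pairwise reweighting factor
#'
#' \eqn{r_{kl} = \sqrt{\rho_k \rho_l}} with \eqn{\rho} the unbiased
#' (weighted) density estimate: when samples are resampled to keep a minimum
#' mutual distance their distribution is approximately uniform, and the
#' statistical weight can be replaced by the unbiased density estimator.
#'
#' @param densities K strictly positive unbiased densities
#'   (from [weighted_density()]).
#' @return Symmetric K x K matrix.
#' @export
stke_reweighting <- function(densities) {
  if (any(densities <= 0)) stop("densities must be strictly positive")
  s <- sqrt(densities)
  outer(s, s)
}

.row_normalize_zero_diag <- function(a) {
  diag(a) <- 0
  rs <- rowSums(a)
  if (any(rs <= 0) || any(!is.finite(rs)))
    stop("vanishing row(s) ", paste(which(rs <= 0 | !is.finite(rs)),
                                    collapse = ", "),
         " in transition construction; increase the bandwidth")
  a / rs
}

#' mrse Markov transition matrix
#'
#' A reweighted Gaussian mixture over a bandwidth set:
#' \eqn{p_{kl} \propto \sum_{\varepsilon} r_{kl}
#'   \exp\{-d^2_{kl}/(2\varepsilon)\}},
#' with the diagonal zeroed before row normalization (self-transitions carry
#' no embedding information).
#'
#' @param sq_distances K x K squared-distance matrix.
#' @param bandwidth_set one or more positive bandwidths \eqn{\varepsilon}.
#' @param r K x K reweighting matrix (default: no reweighting).
#' @return Row-stochastic K x K matrix with zero diagonal.
#' @export
mrse_transition_matrix <- function(sq_distances, bandwidth_set, r = NULL) {
  if (length(bandwidth_set) < 1 || any(bandwidth_set <= 0))
    stop("need at least one positive bandwidth")
  a <- 0
  for (eps in bandwidth_set) a <- a + exp(-sq_distances / (2 * eps))
  if (!is.null(r)) a <- a * r
  .row_normalize_zero_diag(a)
}

#' stke Markov transition matrix
#'
#' Single-bandwidth reweighted Gaussian transition matrix
#' \eqn{p_{kl} \propto r_{kl} \exp\{-d^2_{kl}/(2\varepsilon)\}}; the k-th
#' reweighting term cancels during row normalization.
#'
#' @param sq_distances K x K squared-distance matrix.
#' @param epsilon positive bandwidth.
#' @param r K x K reweighting matrix (default: no reweighting).
#' @return Row-stochastic K x K matrix with zero diagonal.
#' @export
stke_transition_matrix <- function(sq_distances, epsilon, r = NULL) {
  mrse_transition_matrix(sq_distances, epsilon, r)
}

#' Square-root transition matrix
#'
#' \eqn{p_{kl} \propto \sqrt{\rho_l / \rho_k}\, G_{kl}}, the form of the
#' square-root approximation of the infinitesimal generator of the
#' Fokker-Planck operator; it is what the stke construction reduces to under
#' the normalization approximation, and after row normalization the two
#' coincide (the row factor \eqn{\rho_k^{-1/2}} cancels).
#'
#' @param densities K strictly positive densities.
#' @param kernel_matrix K x K Gaussian kernel matrix.
#' @return Row-stochastic K x K matrix with zero diagonal.
#' @export
square_root_transition <- function(densities, kernel_matrix) {
  if (any(densities <= 0)) stop("densities must be strictly positive")
  s <- sqrt(densities)
  .row_normalize_zero_diag(kernel_matrix * outer(1 / s, s))
}

#' Low-dimensional transition matrix Q
#'
#' Row-stochastic transition probabilities between embedded samples:
#' a unit-bandwidth Gaussian \eqn{q_{kl} \propto e^{-\|z_k - z_l\|^2/2}}
#' (the scale is absorbed by the trained map), or the heavy-tailed
#' one-degree-of-freedom t-distribution
#' \eqn{q_{kl} \propto (1 + \|z_k - z_l\|^2)^{-1}} that alleviates the
#' crowding problem. Diagonal zeroed before row normalization.
#'
#' @param z K x d matrix of embedded samples.
#' @param kind `"gaussian"` or `"t_student"`.
#' @return Row-stochastic K x K matrix with zero diagonal.
#' @export
low_dim_q <- function(z, kind = c("gaussian", "t_student")) {
  kind <- match.arg(kind)
  d2 <- pairwise_sq_distances(z)
  e <- if (kind == "gaussian") exp(-d2 / 2) else 1 / (1 + d2)
  .row_normalize_zero_diag(e)
}

#' Kullback-Leibler divergence between transition matrices
#'
#' \eqn{D_{KL}(P \| Q) = \sum_k \sum_{l \ne k} p_{kl}
#'   \ln(p_{kl} / q_{kl})}: the row-wise divergence summed over rows
#' (diagonals excluded). Non-negative; zero iff \eqn{P = Q}.
#'
#' @param p,q row-stochastic matrices of matching shape.
#' @return A single non-negative number.
#' @export
kl_divergence <- function(p, q) {
  if (!all(dim(p) == dim(q))) stop("P and Q must have matching shapes")
  off <- !diag(TRUE, nrow(p))
  pp <- p[off]
  qq <- q[off]
  act <- pp > 0
  if (any(qq[act] <= 0)) stop("Q has zero entries where P is positive")
  sum(pp[act] * (log(pp[act]) - log(qq[act])))
}

#' Cross-entropy between transition matrices
#'
#' \eqn{H(P, Q) = -\sum_k \sum_{l \ne k} p_{kl} \ln q_{kl}}; minimizing it in
#' Q is equivalent to minimizing the KL divergence since
#' \eqn{D_{KL}(P\|Q) = H(P, Q) - H(P, P)}.
#'
#' @inheritParams kl_divergence
#' @return A single number.
#' @export
cross_entropy <- function(p, q) {
  if (!all(dim(p) == dim(q))) stop("P and Q must have matching shapes")
  off <- !diag(TRUE, nrow(p))
  pp <- p[off]
  qq <- q[off]
  act <- pp > 0
  if (any(qq[act] <= 0)) stop("Q has zero entries where P is positive")
  -sum(pp[act] * log(qq[act]))
}

#' Automatic bandwidth set
#'
#' A deterministic geometric grid of `count` bandwidths between the 5th and
#' 75th percentile of the off-diagonal pairwise distances, covering the
#' local-to-mesoscale neighborhood structure of the data; `count = 1` returns
#' the geometric midpoint of the two percentiles.
#'
#' @param sq_distances K x K squared-distance matrix.
#' @param count number of bandwidths (default 4).
#' @return Increasing positive bandwidths of length `count`.
#' @export
select_bandwidths <- function(sq_distances, count = 4) {
  stopifnot(count >= 1)
  d <- sqrt(sq_distances[upper.tri(sq_distances)])
  qs <- stats::quantile(d, c(0.05, 0.75), names = FALSE, type = 7)
  if (qs[1] <= 0) qs[1] <- min(d[d > 0])
  if (count == 1) return(sqrt(qs[1] * qs[2]))
  exp(seq(log(qs[1]), log(qs[2]), length.out = count))
}

#' Landmark subsampling by farthest-point sampling
#'
#' Greedy farthest-point selection seeded at the highest-weight sample: each
#' further landmark is the sample farthest (in Euclidean distance) from the
#' already-selected set. The minimum pairwise distance of the selected set is
#' non-increasing in `m`, so the landmarks cover the sampled manifold nearly
#' uniformly -- the resampling regime in which the stke density
#' approximation holds. Deterministic.
#'
#' @param dataset a [trajectory_dataset()].
#' @param m number of landmarks (`m = K` returns all samples).
#' @return The subset `trajectory_dataset`; selected indices (in selection
#'   order) are stored in `metadata$landmark_indices`.
#' @export
landmark_subsample <- function(dataset, m) {
  stopifnot(inherits(dataset, "trajectory_dataset"))
  k <- n_samples(dataset)
  if (m > k) stop("m exceeds the number of samples")
  if (m == k) {
    dataset$metadata$landmark_indices <- seq_len(k)
    return(dataset)
  }
  x <- dataset$samples
  sel <- integer(m)
  sel[1] <- which.max(dataset$weights)
  d_min <- rowSums(sweep(x, 2, x[sel[1], ], "-")^2)
  if (m > 1) {
    for (i in 2:m) {
      sel[i] <- which.max(d_min)
      d_new <- rowSums(sweep(x, 2, x[sel[i], ], "-")^2)
      d_min <- pmin(d_min, d_new)
    }
  }
  out <- subset_dataset(dataset, sel)
  out$metadata$landmark_indices <- sel
  out
}

#' Embedding configuration for mrse / stke
#'
#' @param method `"mrse"` (multiscale reweighted stochastic embedding) or
#'   `"stke"` (stochastic kinetic embedding).
#' @param n_dim embedding dimension d (default 2).
#' @param bandwidths bandwidth set for mrse (`NULL`: automatic via
#'   [select_bandwidths()]), or a single \eqn{\varepsilon} for stke
#'   (`NULL`: median distance).
#' @param n_bandwidths size of the automatic mrse bandwidth set (default 4).
#' @param low_dim_kernel kernel for Q; defaults to the method's native
#'   choice (`t_student` for mrse, `gaussian` for stke).
#' @param loss `"kl"` or `"cross_entropy"` (equivalent up to the constant
#'   \eqn{H(P,P)}).
#' @param landmarks number of farthest-point landmarks (default 1000).
#' @param hidden hidden layer widths (default `c(64, 64)`).
#' @param epochs training epochs (default 1000).
#' @param batch_rows rows of P per minibatch (default 256).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed RNG seed for initialization and minibatch order.
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(method = c("mrse", "stke"), n_dim = 2,
                             bandwidths = NULL, n_bandwidths = 4,
                             low_dim_kernel = NULL,
                             loss = c("kl", "cross_entropy"),
                             landmarks = 1000, hidden = c(64, 64),
                             epochs = 1000, batch_rows = 256,
                             learning_rate = 1e-3, seed = 1L) {
  method <- match.arg(method)
  loss <- match.arg(loss)
  if (is.null(low_dim_kernel))
    low_dim_kernel <- if (method == "mrse") "t_student" else "gaussian"
  low_dim_kernel <- match.arg(low_dim_kernel, c("t_student", "gaussian"))
  if (!is.null(bandwidths) && any(bandwidths <= 0))
    stop("bandwidths must be positive")
  structure(list(method = method, n_dim = n_dim, bandwidths = bandwidths,
                 n_bandwidths = n_bandwidths, low_dim_kernel = low_dim_kernel,
                 loss = loss, landmarks = landmarks, hidden = hidden,
                 epochs = epochs, batch_rows = batch_rows,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "embedding_config")
}

#' High-dimensional transition matrix P for a stochastic embedding
#'
#' Builds the method's reweighted transition matrix from a (landmark)
#' dataset: mrse uses the geometric-mean weight reweighting over a bandwidth
#' set; stke uses the density reweighting at a single bandwidth.
#'
#' @param dataset a [trajectory_dataset()] (typically landmarks).
#' @param config an [embedding_config()].
#' @return A list with `p` (row-stochastic K x K), and the `bandwidths` used.
#' @export
embedding_transition_matrix <- function(dataset, config) {
  d2 <- pairwise_sq_distances(dataset$samples)
  w <- dataset$weights
  if (config$method == "mrse") {
    bw <- if (is.null(config$bandwidths))
      select_bandwidths(d2, config$n_bandwidths) else config$bandwidths
    p <- mrse_transition_matrix(d2, bw, mrse_reweighting(w))
  } else {
    bw <- if (is.null(config$bandwidths)) epsilon_from_median(d2)
      else config$bandwidths[1]
    g <- gaussian_kernel(d2, bw)
    rho <- weighted_density(g, w)
    p <- stke_transition_matrix(d2, bw, stke_reweighting(rho))
  }
  list(p = p, bandwidths = bw)
}

#' Train a parametric stochastic embedding (mrse / stke)
#'
#' Fits a neural-network target mapping \eqn{\xi_\theta : R^n \to R^d} by
#' minimizing the Kullback-Leibler divergence between the reweighted
#' high-dimensional transition matrix P (fixed during training) and the
#' low-dimensional transition matrix Q computed from the mapped samples.
#' Training is plain minibatch gradient descent with Adam over rows of P;
#' each epoch visits every row exactly once. Deterministic given the
#' config's seed.
#'
#' @param dataset a [trajectory_dataset()]; if larger than
#'   `config$landmarks`, farthest-point landmarks are selected first.
#' @param config an [embedding_config()].
#' @return An object of class `parametric_map` carrying the network
#'   parameters, the input standardization, the training record (loss per
#'   epoch, the entropy floor \eqn{H(P,P)}, seed, bandwidths) and the
#'   landmark dataset. Apply it with `predict()`.
#' @export
train_embedding <- function(dataset, config = embedding_config()) {
  stopifnot(inherits(dataset, "trajectory_dataset"),
            inherits(config, "embedding_config"))
  if (n_samples(dataset) > config$landmarks)
    dataset <- landmark_subsample(dataset, config$landmarks)
  k <- n_samples(dataset)
  if (k < 16) stop("need at least 16 training samples")
  set.seed(config$seed)
  tp <- embedding_transition_matrix(dataset, config)
  p <- tp$p
  # standardize inputs for stable optimization; stored for prediction
  ctr <- colMeans(dataset$samples)
  scl <- apply(dataset$samples, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(dataset$samples, 2, ctr), 2, scl, "/")
  n_in <- ncol(xs)
  layers <- .net_init(n_in, config$hidden, config$n_dim)
  adam <- .adam_init(layers)
  h_pp <- cross_entropy(p, p) # entropy floor: D_KL = H(P,Q) - H(P,P)
  loss_trace <- numeric(config$epochs)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    rows <- sample.int(k)
    batches <- split(rows, ceiling(seq_along(rows) / config$batch_rows))
    epoch_loss <- 0
    for (b in batches) {
      fwd <- .net_forward(layers, xs)
      z <- fwd$output
      d2z <- pairwise_sq_distances(z)
      e <- if (config$low_dim_kernel == "gaussian") exp(-d2z / 2)
        else 1 / (1 + d2z)
      diag(e) <- 0
      q_rows <- e[b, , drop = FALSE] / rowSums(e[b, , drop = FALSE])
      p_rows <- p[b, , drop = FALSE]
      act <- p_rows > 0
      batch_kl <- sum(p_rows[act] * (log(p_rows[act]) - log(q_rows[act])))
      if (!is.finite(batch_kl))
        stop("non-finite loss (bandwidths: ",
             paste(signif(tp$bandwidths, 4), collapse = ", "),
             "; weight range: ", paste(signif(range(dataset$weights), 3),
                                       collapse = " - "), ")")
      epoch_loss <- epoch_loss +
        if (config$loss == "kl") batch_kl else batch_kl + h_pp
      # dL/d(d2z): (q - p) * dlog(e)/d(d2z), nonzero only on batch rows
      gmat <- matrix(0, k, k)
      gkl <- if (config$low_dim_kernel == "gaussian") -0.5
        else -e[b, , drop = FALSE]
      gmat[b, ] <- (q_rows - p_rows) * gkl
      diag(gmat) <- 0
      # d(d2z_kl)/dz_k = 2 (z_k - z_l): accumulate symmetric contributions
      gsym <- gmat + t(gmat)
      dz <- 2 * (z * rowSums(gsym) - gsym %*% z)
      grads <- .net_backward(layers, fwd$acts, dz)
      step <- step + 1L
      upd <- .adam_step(layers, grads, adam, step, config$learning_rate)
      layers <- upd$layers
      adam <- upd$state
    }
    loss_trace[epoch] <- epoch_loss
  }
  structure(list(input_dim = n_in, output_dim = config$n_dim,
                 hidden = config$hidden, activation = "tanh",
                 layers = layers, center = ctr, scale = scl,
                 config = config,
                 training = list(loss = loss_trace, entropy_floor = h_pp,
                                 seed = config$seed,
                                 bandwidths = tp$bandwidths),
                 landmarks = dataset),
            class = "parametric_map")
}

#' Apply a trained target mapping
#'
#' @param object a `parametric_map` from [train_embedding()].
#' @param newdata K x n matrix (or a [trajectory_dataset()]) to embed.
#' @param ... unused.
#' @return K x d matrix of embedded coordinates.
#' @export
predict.parametric_map <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "trajectory_dataset")) newdata$samples
    else as.matrix(newdata)
  if (ncol(x) != object$input_dim)
    stop("newdata has ", ncol(x), " columns; map expects ",
         object$input_dim)
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  .net_forward(object$layers, xs)$output
}

#' @export
print.parametric_map <- function(x, ...) {
  cat("Parametric map (", x$config$method, "): R^", x$input_dim,
      " -> R^", x$output_dim, ", hidden ",
      paste(x$hidden, collapse = "x"), " tanh\n", sep = "")
  n <- length(x$training$loss)
  cat("  final loss:", signif(x$training$loss[n], 5),
      "(entropy floor", signif(x$training$entropy_floor, 5), ")\n")
  invisible(x)
}
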