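# Independent brute-force oracles and shared fixtures. Every oracle here is
# written as plain loops over the defining formulas, deliberately avoiding
# the vectorized code paths it is used to check.

oracle_pairwise_sq <- function(x) {
  x <- as.matrix(x)
  k <- nrow(x)
  d2 <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    d2[i, j] <- sum((x[i, ] - x[j, ])^2)
  d2
}

oracle_density <- function(g, w = rep(1, nrow(g))) {
  k <- nrow(g)
  rho <- numeric(k)
  for (i in seq_len(k)) for (j in seq_len(k))
    rho[i] <- rho[i] + w[j] * g[i, j]
  rho
}

# triple-loop reweighted Markov matrix from the defining formulas
oracle_markov <- function(x, w, eps, mode = "diffusion", alpha = 0.5) {
  d2 <- oracle_pairwise_sq(x)
  k <- nrow(d2)
  g <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    g[i, j] <- exp(-d2[i, j] / (2 * eps))
  rho_v <- oracle_density(g)
  r <- matrix(1, k, k)
  if (mode == "diffusion") {
    for (i in seq_len(k)) for (j in seq_len(k))
      r[i, j] <- w[j] / sqrt(w[i] * rho_v[i] * w[j] * rho_v[j])
  } else if (mode == "geometric_mean") {
    for (i in seq_len(k)) for (j in seq_len(k))
      r[i, j] <- sqrt(w[i] * w[j])
  } else if (mode == "density") {
    rho <- oracle_density(g, w)
    for (i in seq_len(k)) for (j in seq_len(k))
      r[i, j] <- sqrt(rho[i] * rho[j])
  } else if (mode == "none") {
    for (i in seq_len(k)) for (j in seq_len(k))
      r[i, j] <- 1 / (rho_v[i]^alpha * rho_v[j]^alpha)
  }
  m <- matrix(0, k, k)
  for (i in seq_len(k)) {
    s <- 0
    for (j in seq_len(k)) s <- s + r[i, j] * g[i, j]
    for (j in seq_len(k)) m[i, j] <- r[i, j] * g[i, j] / s
  }
  m
}

# zero-diagonal row-normalized mixture kernel (mrse/stke form)
oracle_mixture_transition <- function(d2, bandwidths, r = NULL) {
  k <- nrow(d2)
  a <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    for (eps in bandwidths)
      a[i, j] <- a[i, j] + exp(-d2[i, j] / (2 * eps))
    if (!is.null(r)) a[i, j] <- a[i, j] * r[i, j]
  }
  for (i in seq_len(k)) a[i, ] <- a[i, ] / sum(a[i, ])
  a
}

oracle_low_dim_q <- function(z, kind) {
  d2 <- oracle_pairwise_sq(z)
  k <- nrow(d2)
  e <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    e[i, j] <- if (kind == "gaussian") exp(-d2[i, j] / 2)
      else 1 / (1 + d2[i, j])
  }
  for (i in seq_len(k)) e[i, ] <- e[i, ] / sum(e[i, ])
  e
}

oracle_kl <- function(p, q) {
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (i == j || p[i, j] == 0) next
    s <- s + p[i, j] * log(p[i, j] / q[i, j])
  }
  s
}

# left stationary vector by straight power iteration (independent of eigen)
oracle_stationary <- function(m, iters = 20000) {
  p <- rep(1 / nrow(m), nrow(m))
  for (i in seq_len(iters)) {
    p_new <- as.numeric(t(m) %*% p)
    p_new <- p_new / sum(p_new)
    if (max(abs(p_new - p)) < 1e-15) return(p_new)
    p <- p_new
  }
  p
}

# random reversible row-stochastic chain built from a symmetric affinity
random_reversible_chain <- function(k, seed) {
  set.seed(seed)
  a <- matrix(runif(k * k, 0.05, 1), k, k)
  a <- (a + t(a)) / 2
  a / rowSums(a)
}

# three well-separated Gaussian clusters in n_dim dimensions with
# biased-looking weights; the standard structure-recovery fixture
make_cluster_fixture <- function(k_per = 100, sep = 10, n_dim = 10,
                                 seed = 1) {
  set.seed(seed)
  centers <- matrix(0, 3, n_dim)
  centers[2, 1] <- sep
  centers[3, 2] <- sep
  x <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(stats::rnorm(k_per * n_dim), k_per), 2, centers[i, ], "+")))
  w <- exp(stats::runif(nrow(x), -3, 3))
  list(dataset = trajectory_dataset(x, weights = w),
       labels = rep(1:3, each = k_per))
}

# small weighted random dataset for kernel/Markov oracle checks
make_random_dataset <- function(k, n, seed, log_w_range = 3) {
  set.seed(seed)
  x <- matrix(stats::rnorm(k * n), k, n)
  w <- exp(stats::runif(k, -log_w_range, log_w_range))
  trajectory_dataset(x, weights = w)
}
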