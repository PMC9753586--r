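test_that("mrse and stke reweighting factors are geometric means", {
  expect_equal(mrse_reweighting(c(1, 1, 1)), matrix(1, 3, 3))
  expect_equal(diag(mrse_reweighting(c(0.5, 2, 9))), c(0.5, 2, 9))
  expect_equal(mrse_reweighting(c(1, 4))[1, 2], 2)
  expect_equal(stke_reweighting(c(1, 9))[1, 2], 3)
  rho <- exp(stats::runif(8, -2, 2))
  r <- stke_reweighting(rho)
  want <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) want[i, j] <- sqrt(rho[i] * rho[j])
  expect_equal(r, want, tolerance = 1e-14)
  expect_true(isSymmetric(r))
  expect_error(mrse_reweighting(c(1, -1)), "positive")
  expect_error(stke_reweighting(c(0, 1)), "positive")
})

test_that("mrse/stke transition matrices match the loop oracle and reduce
           to the plain kernel under uniform reweighting", {
  set.seed(7)
  x <- matrix(stats::rnorm(20), 10, 2)
  d2 <- pairwise_sq_distances(x)
  # uniform r: identical to no reweighting at all
  p_plain <- mrse_transition_matrix(d2, 0.8)
  p_unif <- mrse_transition_matrix(d2, 0.8, matrix(3, 10, 10))
  expect_equal(p_plain, p_unif, tolerance = 1e-14)
  expect_equal(rowSums(p_plain), rep(1, 10), tolerance = 1e-14)
  expect_true(all(diag(p_plain) == 0))
  # two bandwidths with reweighting against the brute-force oracle
  w <- exp(stats::runif(10, -2, 2))
  r <- mrse_reweighting(w)
  p2 <- mrse_transition_matrix(d2, c(0.4, 1.6), r)
  expect_equal(p2, oracle_mixture_transition(d2, c(0.4, 1.6), r),
               tolerance = 1e-12)
  # stke is the single-bandwidth case
  rho <- weighted_density(gaussian_kernel(d2, 0.9), w)
  rs <- stke_reweighting(rho)
  ps <- stke_transition_matrix(d2, 0.9, rs)
  expect_equal(ps, oracle_mixture_transition(d2, 0.9, rs),
               tolerance = 1e-12)
  expect_error(mrse_transition_matrix(d2, numeric()), "bandwidth")
})

test_that("square-root transition agrees with stke after normalization", {
  set.seed(3)
  x <- matrix(stats::rnorm(16), 8, 2)
  d2 <- pairwise_sq_distances(x)
  g <- gaussian_kernel(d2, 0.7)
  # uniform density: plain normalized kernel
  expect_equal(square_root_transition(rep(2, 8), g),
               mrse_transition_matrix(d2, 0.7), tolerance = 1e-14)
  # 2-state hand case: each row has one off-diagonal entry, so rows are
  # delta distributions regardless of the density ratio
  g2 <- gaussian_kernel(pairwise_sq_distances(c(0, 1)), 1)
  expect_equal(square_root_transition(c(1, 4), g2),
               matrix(c(0, 1, 1, 0), 2), tolerance = 1e-14)
  # 3-state hand case evaluated directly from the defining formula
  rho <- c(1, 4, 9)
  g3 <- gaussian_kernel(pairwise_sq_distances(c(0, 0.5, 1.2)), 0.6)
  want <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    if (i != j) want[i, j] <- sqrt(rho[j] / rho[i]) * g3[i, j]
  want <- want / rowSums(want)
  expect_equal(square_root_transition(rho, g3), want, tolerance = 1e-14)
  # row factors cancel: identical to stke's geometric-mean form
  expect_equal(square_root_transition(rho, g3),
               stke_transition_matrix(pairwise_sq_distances(c(0, 0.5, 1.2)),
                                      0.6, stke_reweighting(rho)),
               tolerance = 1e-13)
})

test_that("low-dimensional Q kernels have their closed-form values", {
  # coincident samples: uniform over the K-1 neighbors
  q <- low_dim_q(matrix(0, 3, 2), "gaussian")
  expect_equal(q, matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3),
               tolerance = 1e-14)
  # t kernel at squared distance 1 is half its value at 0
  expect_equal(1 / (1 + 1), 0.5)
  z <- matrix(c(0, 1, 5), 3, 1)
  qt <- low_dim_q(z, "t_student")
  raw <- 1 / (1 + pairwise_sq_distances(z))
  diag(raw) <- 0
  expect_equal(qt, raw / rowSums(raw), tolerance = 1e-14)
  # random case against the loop oracle
  set.seed(2)
  z8 <- matrix(stats::rnorm(16), 8, 2)
  for (kind in c("gaussian", "t_student"))
    expect_equal(low_dim_q(z8, kind), oracle_low_dim_q(z8, kind),
                 tolerance = 1e-13)
})

test_that("KL divergence and cross-entropy satisfy their identities", {
  set.seed(4)
  z <- matrix(stats::rnorm(12), 6, 2)
  p <- low_dim_q(z, "gaussian")
  q <- low_dim_q(z + 0.3 * matrix(stats::rnorm(12), 6, 2), "gaussian")
  expect_equal(kl_divergence(p, p), 0)
  expect_gt(kl_divergence(p, q), 0)
  expect_equal(kl_divergence(matrix(c(0, 1, 1, 0), 2),
                             matrix(c(0, 1, 1, 0), 2)), 0)
  # hand case against the loop oracle
  expect_equal(kl_divergence(p, q), oracle_kl(p, q), tolerance = 1e-13)
  # D_KL = H(P, Q) - H(P, P)
  expect_equal(kl_divergence(p, q),
               cross_entropy(p, q) - cross_entropy(p, p),
               tolerance = 1e-12)
  qz <- q; qz[1, 2] <- 0
  expect_error(kl_divergence(p, qz), "zero")
})

test_that("automatic bandwidths form a monotone geometric grid between
           distance percentiles", {
  set.seed(6)
  x <- matrix(stats::rnorm(80), 40, 2)
  d2 <- pairwise_sq_distances(x)
  d <- sort(sqrt(d2[upper.tri(d2)]))
  q5 <- stats::quantile(d, 0.05, names = FALSE)
  q75 <- stats::quantile(d, 0.75, names = FALSE)
  bw <- select_bandwidths(d2, 4)
  expect_length(bw, 4)
  expect_true(all(diff(bw) > 0))
  expect_equal(bw[1], q5, tolerance = 1e-12)
  expect_equal(bw[4], q75, tolerance = 1e-12)
  # geometric: constant ratio between consecutive bandwidths
  expect_lt(diff(range(diff(log(bw)))), 1e-12)
  expect_equal(select_bandwidths(d2, 1), sqrt(q5 * q75), tolerance = 1e-12)
})

test_that("farthest-point landmarks start at the highest weight and cover
           extremes", {
  x <- matrix(seq(0, 9), ncol = 1)
  w <- c(10, rep(1, 9)) # highest weight at the left end
  ds <- trajectory_dataset(x, weights = w)
  # m = K returns everything
  all_ds <- landmark_subsample(ds, 10)
  expect_equal(n_samples(all_ds), 10)
  expect_equal(all_ds$samples, ds$samples)
  # m = 1: the highest-weight sample
  one <- landmark_subsample(ds, 1)
  expect_equal(one$samples[1, 1], 0)
  # m = 2 on a line anchored at an extreme: the two extreme points
  two <- landmark_subsample(ds, 2)
  expect_setequal(two$samples[, 1], c(0, 9))
  # minimum pairwise distance of the subset is non-increasing in m
  set.seed(8)
  ds2 <- make_random_dataset(60, 3, seed = 8)
  min_d <- sapply(c(5, 10, 20, 40), function(m) {
    s <- landmark_subsample(ds2, m)
    d2 <- pairwise_sq_distances(s$samples)
    sqrt(min(d2[upper.tri(d2)]))
  })
  expect_true(all(diff(min_d) <= 1e-12))
})

test_that("training reduces the loss toward the entropy floor and is
           bit-reproducible", {
  # data already two-dimensional: an identity-capable map can match P
  set.seed(5)
  x <- matrix(stats::rnorm(120), 60, 2)
  ds <- trajectory_dataset(x)
  cfg <- embedding_config(method = "mrse", n_dim = 2, landmarks = 60,
                          epochs = 120, batch_rows = 60, seed = 12)
  map <- train_embedding(ds, cfg)
  tr <- map$training$loss
  expect_true(all(is.finite(tr)))
  expect_true(all(tr >= 0)) # KL loss is non-negative
  expect_lt(tr[length(tr)], tr[1])
  expect_lt(tr[length(tr)], 0.2 * tr[1]) # close to the D_KL = 0 floor
  # identical seed, identical trace
  map2 <- train_embedding(ds, cfg)
  expect_identical(map$training$loss, map2$training$loss)
  expect_identical(map$layers, map2$layers)
  # prediction is deterministic given parameters
  expect_identical(predict(map, ds), predict(map2, ds))
})

test_that("with unit weights the mrse matrix equals the plain multiscale
           kernel exactly", {
  set.seed(10)
  ds <- trajectory_dataset(matrix(stats::rnorm(60), 30, 2))
  cfg <- embedding_config(method = "mrse", landmarks = 30)
  tp <- embedding_transition_matrix(ds, cfg)
  d2 <- pairwise_sq_distances(ds$samples)
  expect_equal(tp$p, mrse_transition_matrix(d2, tp$bandwidths),
               tolerance = 1e-15)
})

test_that("reweighted embedding recovers equilibrium well free energies
           from biased data; the non-reweighted profile compresses them", {
  pot <- model_potential(c(12, 8, 5), c(-2.5, 0, 2.5), c(0.4, 0.5, 0.6),
                         c(-4, 4))
  ds <- suppressMessages(run_biased_simulation(
    pot, langevin_config(n_steps = 2e6, stride = 10, seed = 21),
    metad_config(bias_factor = 5, initial_height = 0.8)))
  set.seed(4)
  sub <- subset_dataset(ds, sort(sample.int(n_samples(ds), 3000)))
  x1 <- sub$samples[, 1]
  # lift to 5D with uninformative noise dimensions
  lift <- cbind(x1, matrix(stats::rnorm(length(x1) * 4, sd = 0.3),
                           ncol = 4))
  ds5 <- trajectory_dataset(lift, weights = sub$weights)
  lab <- ifelse(x1 < -1.2, 1L, ifelse(x1 < 1.2, 2L, 3L))
  profile_at_wells <- function(z, hw) {
    br <- seq(min(z), max(z), length.out = 61)
    bin <- cut(z, br, include.lowest = TRUE, labels = FALSE)
    f_bin <- -log(tapply(hw, bin, sum))
    zw <- sapply(1:3, function(j) stats::median(z[lab == j]))
    fw <- f_bin[as.character(cut(zw, br, include.lowest = TRUE,
                                 labels = FALSE))]
    unname(fw - min(f_bin, na.rm = TRUE))
  }
  cfg <- embedding_config(method = "mrse", n_dim = 1, landmarks = 400,
                          epochs = 150, batch_rows = 128, seed = 9)
  # reweighted pipeline: weighted training + weighted histogram
  map_rw <- train_embedding(ds5, cfg)
  f_rw <- profile_at_wells(predict(map_rw, ds5)[, 1], ds5$weights)
  # non-reweighted pipeline: unit weights throughout
  ds5u <- ds5
  ds5u$weights <- rep(1, n_samples(ds5))
  map_u <- train_embedding(ds5u, cfg)
  f_u <- profile_at_wells(predict(map_u, ds5u)[, 1],
                          rep(1, n_samples(ds5)))
  df21 <- evaluate_potential(pot, 0) - evaluate_potential(pot, -2.5)
  df31 <- evaluate_potential(pot, 2.5) - evaluate_potential(pot, -2.5)
  # the reweighted profile orders the wells correctly and reproduces the
  # analytic free-energy differences
  expect_true(f_rw[1] < f_rw[2] && f_rw[2] < f_rw[3])
  expect_equal(f_rw[2] - f_rw[1], df21, tolerance = 0.4)
  expect_equal(f_rw[3] - f_rw[1], df31, tolerance = 0.3)
  # the non-reweighted profile reflects the biased (tempered) landscape:
  # well differences compressed by roughly the bias factor
  expect_lt(f_u[3] - f_u[1], 0.5 * df31)
})
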