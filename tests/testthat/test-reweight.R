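test_that("pairwise squared distances match the defining double loop", {
  expect_equal(pairwise_sq_distances(matrix(2.5)), matrix(0))
  expect_equal(pairwise_sq_distances(c(0, 3))[1, 2], 9)
  x <- matrix(stats::rnorm(60), 20, 3)
  d2 <- pairwise_sq_distances(x)
  expect_equal(d2, oracle_pairwise_sq(x), tolerance = 1e-12)
  expect_true(isSymmetric(d2))
  expect_true(all(diag(d2) == 0))
  expect_error(pairwise_sq_distances(matrix(c(1, NA), 2)), "finite")
})

test_that("gaussian kernel follows the exp(-d^2/(2 eps)) convention", {
  d2 <- pairwise_sq_distances(matrix(stats::rnorm(30), 10, 3))
  g <- gaussian_kernel(d2, 0.7)
  expect_equal(diag(g), rep(1, 10))
  expect_true(isSymmetric(g))
  expect_equal(gaussian_kernel(matrix(2 * 0.7), 0.7)[1, 1], exp(-1))
  expect_error(gaussian_kernel(d2, 0), "positive")
})

test_that("median heuristic returns the median off-diagonal distance", {
  # a distance multiset {1, 2, 9} has median 2
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 1
  d[1, 3] <- d[3, 1] <- 2
  d[2, 3] <- d[3, 2] <- 9
  expect_equal(epsilon_from_median(d^2), 2)
  # uniform distances
  du <- matrix(1, 3, 3); diag(du) <- 0
  expect_equal(epsilon_from_median(du^2), 1)
  # random set against a sort-based oracle
  x <- matrix(stats::rnorm(24), 12, 2)
  d2 <- pairwise_sq_distances(x)
  all_d <- sort(sqrt(d2[upper.tri(d2)]))
  expect_equal(epsilon_from_median(d2), stats::median(all_d))
  expect_error(epsilon_from_median(matrix(0)), "two samples")
})

test_that("biased and weighted densities match their loop oracles", {
  expect_equal(biased_density(matrix(1)), 1)
  expect_equal(weighted_density(matrix(1), 5), 5)
  # two coincident samples see each other fully
  g2 <- gaussian_kernel(pairwise_sq_distances(c(1, 1)), 1)
  expect_equal(biased_density(g2), c(2, 2))
  ds <- make_random_dataset(30, 2, seed = 8)
  g <- gaussian_kernel(pairwise_sq_distances(ds$samples), 0.9)
  expect_equal(biased_density(g), oracle_density(g), tolerance = 1e-13)
  expect_equal(weighted_density(g, ds$weights),
               oracle_density(g, ds$weights), tolerance = 1e-13)
  # uniform weights reduce the weighted to the biased density exactly
  expect_equal(weighted_density(g, rep(1, 30)), biased_density(g),
               tolerance = 1e-15)
  expect_error(weighted_density(g, rep(-1, 30)), "positive")
})

test_that("anisotropic kernel divides by density powers", {
  g <- gaussian_kernel(pairwise_sq_distances(matrix(stats::rnorm(20), 10)),
                       1.2)
  rho <- biased_density(g)
  expect_identical(anisotropic_kernel(g, rho, 0), g)
  expect_equal(anisotropic_kernel(g, rep(2, 10), 0.5), g / 2,
               tolerance = 1e-15)
  a <- anisotropic_kernel(g, rho, 0.5)
  want <- g
  for (i in 1:10) for (j in 1:10)
    want[i, j] <- g[i, j] / (sqrt(rho[i]) * sqrt(rho[j]))
  expect_equal(a, want, tolerance = 1e-14)
  expect_warning(anisotropic_kernel(g, c(0, rho[-1]), 0.5), "floor")
})

test_that("diffusion reweighting factor has its closed-form special cases", {
  # uniform weights and densities: a constant matrix, so M reduces to the
  # plain normalized kernel
  r <- diffusion_reweighting_factor(rep(2, 5), rep(3, 5))
  expect_true(max(abs(r - r[1, 1])) < 1e-15)
  # general form at alpha = 1/2 with unit densities: diagonal is w_k
  w <- c(0.5, 2, 7)
  rg <- diffusion_reweighting_factor(w, densities = rep(1, 3))
  expect_equal(diag(rg), w)
  expect_error(diffusion_reweighting_factor(w, c(1, 1)), "length")
  expect_error(diffusion_reweighting_factor(w, rep(1, 3), alpha = 0.3),
               "alpha")
})

test_that("the final and general reweighting forms give the same M when
           the density substitution is exact", {
  ds <- make_random_dataset(25, 2, seed = 4)
  g <- gaussian_kernel(pairwise_sq_distances(ds$samples), 1.1)
  rho_v <- biased_density(g)
  w <- ds$weights
  # construct unbiased densities satisfying rho = w * rho_V exactly
  rho <- w * rho_v
  r19 <- diffusion_reweighting_factor(w, densities = rho, alpha = 0.5)
  r20 <- diffusion_reweighting_factor(w, rho_v)
  m19 <- (r19 * g) / rowSums(r19 * g)
  m20 <- (r20 * g) / rowSums(r20 * g)
  expect_equal(m19, m20, tolerance = 1e-12)
})

test_that("Markov model matches analytic 2-state and brute-force forms", {
  # K = 2, no reweighting: closed form in the off-diagonal kernel value
  x <- c(0, 1)
  spec <- kernel_spec(epsilon = 0.8, reweighting = "none")
  m <- build_markov_model(x, spec)
  g <- exp(-1 / (2 * 0.8))
  expect_equal(m$transition_matrix,
               matrix(c(1, g, g, 1) / (1 + g), 2, byrow = TRUE),
               tolerance = 1e-14)
  # random weighted K = 40 against the triple-loop oracle, all modes
  ds <- make_random_dataset(40, 3, seed = 12)
  for (mode in c("none", "diffusion", "geometric_mean", "density")) {
    mm <- build_markov_model(ds, kernel_spec(epsilon = 1.4,
                                             reweighting = mode))
    want <- oracle_markov(ds$samples, ds$weights, 1.4, mode, alpha = 0.5)
    expect_equal(mm$transition_matrix, want, tolerance = 1e-12)
    expect_equal(rowSums(mm$transition_matrix), rep(1, 40),
                 tolerance = 1e-12)
  }
})

test_that("unit weights make every reweighted construction collapse to the
           plain one exactly", {
  set.seed(9)
  x <- matrix(stats::rnorm(60), 30, 2)
  ds1 <- trajectory_dataset(x, weights = rep(1, 30))
  # diffusion reweighting at unit weights is the anisotropic (alpha = 1/2)
  # diffusion-map kernel; the geometric-mean (mrse) factor carries no
  # density normalization, so its plain counterpart is the alpha = 0 kernel
  m_aniso <- build_markov_model(x, kernel_spec(epsilon = 1,
                                               reweighting = "none"))
  m_flat <- build_markov_model(x, kernel_spec(epsilon = 1, alpha = 0,
                                              reweighting = "none"))
  m_diff <- build_markov_model(ds1, kernel_spec(epsilon = 1,
                                                reweighting = "diffusion"))
  m_geo <- build_markov_model(ds1, kernel_spec(epsilon = 1,
                                               reweighting = "geometric_mean"))
  expect_equal(m_diff$transition_matrix, m_aniso$transition_matrix,
               tolerance = 1e-15)
  expect_equal(m_geo$transition_matrix, m_flat$transition_matrix,
               tolerance = 1e-15)
})

test_that("row-index factors in r cancel under normalization", {
  ds <- make_random_dataset(30, 2, seed = 3)
  g <- gaussian_kernel(pairwise_sq_distances(ds$samples), 1)
  rho_v <- biased_density(g)
  r <- diffusion_reweighting_factor(ds$weights, rho_v)
  scale_k <- exp(stats::runif(30, -2, 2)) # arbitrary positive row function
  m1 <- (r * g) / rowSums(r * g)
  r2 <- r * scale_k # multiplies row k by scale_k
  m2 <- (r2 * g) / rowSums(r2 * g)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("the reweighted chain is symmetrizable: real spectrum in [-1, 1],
           even for weights spanning many orders of magnitude", {
  for (seed in 1:4) {
    ds <- make_random_dataset(25, 2, seed = seed, log_w_range = 40)
    for (mode in c("none", "diffusion", "geometric_mean", "density")) {
      m <- build_markov_model(ds, kernel_spec(reweighting = mode))
      ev <- eigen(m$transition_matrix, only.values = TRUE)$values
      expect_lt(max(abs(Im(ev))), 1e-8)
      expect_true(all(Re(ev) <= 1 + 1e-10 & Re(ev) >= -1 - 1e-10))
    }
  }
})

test_that("an isolated sample with a vanishing kernel row is reported", {
  x <- c(0, 1e6) # two points too far apart for the kernel scale
  expect_error(build_markov_model(x, kernel_spec(epsilon = 1)),
               "epsilon")
})
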