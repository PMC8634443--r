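# KDE, Kullback-Leibler similarity, binarization.

test_that("KDE moments track the generating distribution", {
  x <- with_test_seed(10, rnorm(10000, 0.5, 0.1))
  d <- estimate_density(x)
  dx <- d$grid[2] - d$grid[1]
  mu <- sum(d$grid * d$density) * dx
  v <- sum((d$grid - mu)^2 * d$density) * dx
  expect_lt(abs(mu - 0.5) / 0.5, 0.02)
  expect_lt(abs(sqrt(v) - 0.1) / 0.1, 0.02)
  # the estimator's variance equals sample variance plus bandwidth^2
  v_oracle <- mean((x - mean(x))^2) + d$bandwidth^2
  expect_lt(abs(v - v_oracle) / v_oracle, 0.01)
})

test_that("density is floored and integrates to one", {
  x <- with_test_seed(11, rnorm(200, 0.5, 0.05))
  d <- estimate_density(x, from = 0, to = 2)   # long empty tail
  expect_true(all(d$density > 0))
  expect_lt(abs(trapz(d$grid, d$density) - 1), 1e-3)
})

test_that("KDE with fixed bandwidth is invariant to sample duplication", {
  x <- with_test_seed(12, rnorm(500, 0.5, 0.1))
  d1 <- estimate_density(x, bandwidth = 0.02, from = 0.1, to = 0.9)
  d2 <- estimate_density(c(x, x), bandwidth = 0.02, from = 0.1, to = 0.9)
  expect_lt(max(abs(d1$density - d2$density)), 1e-6)
})

test_that("degenerate samples error unless jitter is enabled", {
  expect_error(estimate_density(rep(0.5, 10)), "jitter")
  d <- estimate_density(rep(0.5, 10), jitter = TRUE)
  expect_true(all(is.finite(d$density)))
})

test_that("identical distributions give similarity exactly one", {
  x <- with_test_seed(13, rnorm(100, 0.5, 0.1))
  p <- estimate_density(x, from = 0, to = 1)
  expect_identical(kl_similarity(p, p), 1)
  expect_identical(kl_divergence(p, p), 0)
})

test_that("discrete symmetric KL matches the closed-form Gaussian value", {
  # For N(mu1, s^2) vs N(mu2, s^2): KL(p||q) + KL(q||p) = (mu1-mu2)^2 / s^2
  grid <- seq(0.05, 0.95, length.out = 2048)
  mk <- function(mu) {
    y <- dnorm(grid, mu, 0.05)
    y <- pmax(y, 1e-10); y <- y / trapz(grid, y)
    structure(list(grid = grid, density = y, bandwidth = 0.05),
              class = "density_estimate")
  }
  p <- mk(0.4); q <- mk(0.6)
  D <- kl_divergence(p, q)
  closed <- (0.4 - 0.6)^2 / 0.05^2
  expect_lt(abs(D - closed) / closed, 0.02)
  expect_equal(kl_similarity(p, q), exp(-D))
  # symmetry to machine precision
  expect_equal(kl_divergence(p, q), kl_divergence(q, p), tolerance = 1e-14)
  # grid mismatch rejected
  q2 <- mk(0.6); q2$grid <- q2$grid + 1e-3
  expect_error(kl_divergence(p, q2), "identical grid")
})

test_that("similarity decreases as distributions are pulled apart", {
  grid <- seq(-0.5, 1.5, length.out = 1024)
  mk <- function(mu) {
    y <- pmax(dnorm(grid, mu, 0.08), 1e-10)
    structure(list(grid = grid, density = y / trapz(grid, y),
                   bandwidth = 0.08), class = "density_estimate")
  }
  base <- mk(0.5)
  sims <- vapply(seq(0.5, 0.9, by = 0.1),
                 function(mu) kl_similarity(base, mk(mu)), numeric(1))
  expect_true(all(diff(sims) < 0))
  # non-negativity of the divergence on random density pairs
  for (s in 1:10) {
    y1 <- with_test_seed(100 + s, pmax(runif(128), 1e-10))
    y2 <- with_test_seed(200 + s, pmax(runif(128), 1e-10))
    g <- seq(0, 1, length.out = 128)
    d1 <- structure(list(grid = g, density = y1 / trapz(g, y1), bandwidth = 1),
                    class = "density_estimate")
    d2 <- structure(list(grid = g, density = y2 / trapz(g, y2), bandwidth = 1),
                    class = "density_estimate")
    expect_gt(kl_divergence(d1, d2), -1e-12)
  }
})

test_that("similarity matrix is symmetric, unit-diagonal, order-equivariant", {
  nreg <- 12
  samp <- with_test_seed(14, lapply(1:nreg, function(i)
    rnorm(60, runif(1, 0.4, 0.7), 0.1)))
  rs <- structure(list(subject_id = "s", samples = setNames(samp, 1:nreg),
                       region_ids = 1:nreg), class = "regional_samples")
  S <- build_similarity_matrix(rs)
  expect_equal(dim(S$values), c(nreg, nreg))
  expect_lt(max(abs(S$values - t(S$values))), 1e-12)
  expect_equal(diag(S$values), rep(1, nreg))
  expect_true(all(S$values > 0 & S$values <= 1))
  # permutation equivariance: permute input, unpermute output
  perm <- with_test_seed(15, sample(nreg))
  rsp <- structure(list(subject_id = "s",
                        samples = setNames(samp[perm], (1:nreg)[perm]),
                        region_ids = (1:nreg)[perm]),
                   class = "regional_samples")
  Sp <- build_similarity_matrix(rsp)
  inv <- order(perm)
  expect_equal(Sp$values[inv, inv], S$values, tolerance = 1e-14)
  # identical regional distributions give all-1 similarities
  same <- structure(list(subject_id = "s",
                         samples = setNames(rep(samp[1], nreg), 1:nreg),
                         region_ids = 1:nreg), class = "regional_samples")
  expect_equal(unname(build_similarity_matrix(same)$values),
               matrix(1, nreg, nreg))
  # determinism
  expect_identical(build_similarity_matrix(rs)$values, S$values)
})

test_that("binarization keeps floor(s * R(R-1)/2) strongest edges", {
  R <- 90
  W <- with_test_seed(16, {
    w <- matrix(runif(R * R), R, R); w[lower.tri(w, TRUE)] <- 0; w + t(w)
  })
  diag(W) <- 1
  S <- structure(list(subject_id = "s", values = W, region_ids = 1:R),
                 class = "similarity_matrix")
  net <- binarize_at_sparsity(S, 0.05)
  expect_equal(sum(net$adjacency) / 2, 200)   # floor(0.05 * 4005)
  expect_true(all(!diag(net$adjacency)))
  # nesting of edge sets across thresholds (distinct weights)
  n2 <- binarize_at_sparsity(S, 0.07)
  expect_true(all(n2$adjacency[net$adjacency]))
  # sparsity near 1 gives the complete graph
  nall <- binarize_at_sparsity(S, 0.9999)
  expect_equal(sum(nall$adjacency) / 2, floor(0.9999 * R * (R - 1) / 2))
  expect_error(binarize_at_sparsity(S, 1.2), "sparsity")
})

test_that("tie-breaking is deterministic lexicographic", {
  W <- matrix(0.5, 4, 4); diag(W) <- 1
  S <- structure(list(subject_id = "s", values = W, region_ids = 1:4),
                 class = "similarity_matrix")
  net <- binarize_at_sparsity(S, 0.5)   # K = floor(0.5 * 6) = 3, all tied
  e <- which(upper.tri(W) & net$adjacency, arr.ind = TRUE)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  expect_equal(unname(e), cbind(c(1, 1, 1), c(2, 3, 4)))
})

test_that("the default sparsity series has 18 increasing levels", {
  R <- 20
  W <- with_test_seed(17, {
    w <- matrix(runif(R * R), R, R); w[lower.tri(w, TRUE)] <- 0; w + t(w)
  })
  diag(W) <- 1
  S <- structure(list(subject_id = "s", values = W, region_ids = 1:R),
                 class = "similarity_matrix")
  nets <- sparsity_series(S)
  expect_length(nets, 18)
  expect_equal(vapply(nets, `[[`, numeric(1), "sparsity"),
               seq(0.05, 0.39, by = 0.02))
  counts <- vapply(nets, function(n) sum(n$adjacency) / 2, numeric(1))
  expect_true(all(diff(counts) > 0))
  expect_length(sparsity_series(S, 0.1, 0.1, 0.02), 1)
})
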