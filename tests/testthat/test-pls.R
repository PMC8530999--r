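test_that("column standardization hits population moments and flags constants", {
  s <- standardize_columns(matrix(c(1, 2, 3)))
  expect_equal(as.numeric(s$z), c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-6)
  expect_equal(standardize_columns(s$z)$z, s$z, tolerance = 1e-12)
  m <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(standardize_columns(m), "b")
})

test_that("single-behavior PLS reduces to the per-voxel correlation pattern", {
  set.seed(20)
  X <- matrix(rnorm(60 * 15), 60, 15)
  y <- matrix(rnorm(60), 60, 1)
  d <- brain_behavior_data(X, y, rep("g", 60))
  m <- pls_fit(d)
  expect_equal(length(m$d), 1L)
  expect_equal(m$explained, 1)
  r <- as.numeric(cor(X, y))
  expect_equal(abs(cor(m$v[, 1], r)), 1, tolerance = 1e-10)
  # closed form for a 1 x V matrix: singular value = Frobenius norm
  R <- crossprod(standardize_columns(y)$z, standardize_columns(X)$z) / 59
  expect_equal(m$d, sqrt(sum(R^2)), tolerance = 1e-12)
})

test_that("a diagonal cross-correlation gives axis saliences and known fractions", {
  # construct data whose standardized cross-products are exactly diagonal
  set.seed(21)
  n <- 40
  raw <- matrix(rnorm(n * 4), n, 4)
  basis <- qr.Q(qr(sweep(raw, 2, colMeans(raw))))  # orthonormal and mean-zero
  unitize <- function(b) (b - mean(b)) / popsd(b)
  y1 <- unitize(basis[, 1]); y2 <- unitize(basis[, 2])
  w1 <- unitize(basis[, 3]); w2 <- unitize(basis[, 4])
  X <- cbind(0.8 * y1 + sqrt(1 - 0.64) * w1, 0.3 * y2 + sqrt(1 - 0.09) * w2)
  d <- brain_behavior_data(X, cbind(y1, y2), rep("g", n))
  m <- pls_fit(d)
  expect_equal(m$explained, c(0.64, 0.09) / 0.73, tolerance = 1e-10)
  expect_equal(abs(m$u), diag(2), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(abs(m$v), diag(2), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("singular values are invariant to orthogonal behavior rotations", {
  set.seed(22)
  X <- matrix(rnorm(50 * 20), 50, 20)
  Y <- matrix(rnorm(50 * 3), 50, 3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  # whiten the behavior first so the internal re-standardization is a no-op
  # on both sides of the rotation
  Yz <- standardize_columns(Y)$z
  Yw <- Yz %*% solve(chol(crossprod(Yz) / 50))
  m1 <- pls_fit(brain_behavior_data(X, Yw, rep("g", 50)))
  m2 <- pls_fit(brain_behavior_data(X, Yw %*% Q, rep("g", 50)))
  expect_equal(m1$d, m2$d, tolerance = 1e-8)
})

test_that("the SVD factors are orthonormal and energy is conserved", {
  set.seed(23)
  X <- matrix(rnorm(30 * 12), 30, 12)
  Y <- matrix(rnorm(30 * 3), 30, 3)
  m <- pls_fit(brain_behavior_data(X, Y, rep("g", 30)))
  expect_equal(crossprod(m$u), diag(ncol(m$u)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(crossprod(m$v), diag(ncol(m$v)), tolerance = 1e-10,
               ignore_attr = TRUE)
  R <- crossprod(standardize_columns(Y)$z, standardize_columns(X)$z) / 29
  expect_equal(sum(m$d^2), sum(R^2), tolerance = 1e-10)
  expect_equal(sum(m$explained_all), 1, tolerance = 1e-12)
  expect_true(all(diff(m$d) <= 1e-12))
  # sign convention: dominant behavior-salience entry is positive
  for (k in seq_along(m$d)) {
    expect_gt(m$u[which.max(abs(m$u[, k])), k], 0)
  }
})

test_that("first singular value matches brute-force covariance maximization (V = 2)", {
  set.seed(24)
  X <- matrix(rnorm(20 * 2), 20, 2)
  y <- matrix(rnorm(20), 20, 1)
  m <- pls_fit(brain_behavior_data(X, y, rep("g", 20)))
  R <- crossprod(standardize_columns(y)$z, standardize_columns(X)$z) / 19
  theta <- seq(0, 2 * pi, length.out = 200001)
  grid_max <- max(R[1] * cos(theta) + R[2] * sin(theta))
  expect_equal(m$d[1], grid_max, tolerance = 1e-3)
})

test_that("loadings are correlations with the latent scores", {
  pl <- make_planted(seed = 30, n_voxels = 120, noise_sd = 0, deconfound = FALSE)
  m <- pls_fit(pl$data)
  m <- compute_loadings(m, pl$data$X, pl$data$Y)
  sup <- pl$truth$support
  expect_equal(abs(m$brain_loadings[sup, 1]), rep(1, length(sup)),
               tolerance = 1e-6)
  # independent noise voxels stay weakly loaded at N = 166
  pl2 <- make_planted(seed = 31, n_voxels = 200)
  m2 <- compute_loadings(pls_fit(pl2$data), pl2$data$X, pl2$data$Y)
  noise <- setdiff(seq_len(200), pl2$truth$support)
  expect_lt(stats::quantile(abs(m2$brain_loadings[noise, 1]), 0.99), 0.3)
})

test_that("component reports carry score correlation and explained covariance", {
  pl <- make_planted(seed = 32, n_voxels = 100, noise_sd = 0,
                     deconfound = FALSE)
  m <- compute_loadings(pls_fit(pl$data), pl$data$X, pl$data$Y)
  rep1 <- report_component(m, 1)
  expect_gt(rep1$r_scores, 0.99)
  expect_equal(rep1$explained_covariance, m$explained[1])
  expect_error(report_component(m, 9), "out of range")
  expect_error(report_component(list(), 1), "pls_model")
  expect_output(print(rep1), "Latent component 1")
})

test_that("the null cross-correlation is isotropic over behavior coordinates", {
  # under a null, no behavior measure carries preferred covariance energy:
  # the share of ||R||_F^2 attributed to each behavior coordinate averages
  # 1/B (the *ordered* component fractions are upward/downward biased by
  # ordering, so isotropy is asserted on coordinates, not components)
  set.seed(33)
  shares <- replicate(40, {
    X <- matrix(rnorm(60 * 400), 60, 400)
    Y <- matrix(rnorm(60 * 3), 60, 3)
    Xz <- standardize_columns(X)$z
    Yz <- standardize_columns(Y)$z
    R <- crossprod(Yz, Xz) / 59
    rowSums(R^2) / sum(R^2)
  })
  expect_equal(rowMeans(shares), rep(1 / 3, 3), tolerance = 0.1)
  # and the ordered explained fractions still sum to one and are sorted
  m <- pls_fit(brain_behavior_data(matrix(rnorm(60 * 400), 60, 400),
                                   matrix(rnorm(180), 60, 3), rep("g", 60)))
  expect_equal(sum(m$explained_all), 1, tolerance = 1e-12)
  expect_true(all(diff(m$explained) <= 1e-12))
})
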