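test_that("knn weights symmetrize by union and row-standardize", {
  # 3 collinear equidistant points, k = 1: the middle point is the nearest
  # neighbour of both ends, so after union it has both as neighbours
  W <- build_knn_weights(cbind(c(0, 1, 2), c(0, 0, 0)), k = 1)
  expect_equal(W$neighbours[[2]], c(1L, 3L))
  expect_true(all(vapply(W$weights, sum, numeric(1)) == 1))
  # regular grid, k = 4: deep-interior cells (no tie spillover from the
  # boundary) get exactly their rook neighbours at weight 0.25
  g <- expand.grid(x = 1:7, y = 1:7)
  W4 <- build_knn_weights(g, k = 4)
  interior <- which(g$x %in% 3:5 & g$y %in% 3:5)
  for (i in interior) {
    expect_equal(length(W4$neighbours[[i]]), 4L)
    expect_equal(W4$weights[[i]], rep(0.25, 4))
  }
  expect_error(build_knn_weights(cbind(1:3, 1:3), k = 8), "more than k")
})

test_that("queen contiguity links polygons sharing a vertex", {
  sq <- function(i, j) cbind(c(i, i + 1, i + 1, i, i),
                             c(j, j, j + 1, j + 1, j))
  polys <- list(sq(0, 0), sq(1, 0), sq(0, 1), sq(1, 1))
  W <- build_queen_weights(polys)
  # 2x2 block: all pairs share at least the centre vertex
  expect_equal(W$neighbours[[1]], c(2L, 3L, 4L))
  expect_true(all(vapply(W$weights, sum, numeric(1)) == 1))
})

test_that("the correlation filter retains a mutually low-correlation set", {
  set.seed(5)
  x1 <- rnorm(100)
  X <- data.frame(a = x1, b = x1 + rnorm(100, 0, 0.1), c = rnorm(100))
  expect_equal(correlation_filter(X), c("a", "c"))       # |r(a,b)| > 0.7
  expect_equal(correlation_filter(data.frame(a = x1, dup = x1)), "a")
  lowcor <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  expect_equal(correlation_filter(lowcor), c("a", "b", "c"))
  expect_error(correlation_filter(data.frame(a = x1, k = rep(1, 100))),
               "constant")
})

test_that("Moran's I matches the brute-force double sum and ape", {
  set.seed(9)
  pts <- cbind(runif(5, 0, 10), runif(5, 0, 10))
  W <- build_knn_weights(pts, k = 2)
  y <- c(3.2, -1.5, 0.7, 4.4, -2.2)
  res <- morans_i(y, W, n_perm = 99, seed = 1)
  expect_equal(res$i_value, brute_moran(y, W), tolerance = 1e-12)
  expect_equal(res$expected, -1 / 4)
  skip_if_not_installed("ape")
  expect_equal(res$i_value,
               ape::Moran.I(y, weights_matrix(W))$observed,
               tolerance = 1e-10)
})

test_that("Moran's I is negative on a checkerboard and seeded perms repeat", {
  g <- expand.grid(x = 1:6, y = 1:6)
  W <- build_knn_weights(g, k = 4)
  y <- (-1)^(g$x + g$y)
  res <- morans_i(y, W, n_perm = 199, seed = 3)
  expect_lt(res$i_value, 0)
  expect_lt(res$p_perm, 0.05)
  res2 <- morans_i(y, W, n_perm = 199, seed = 3)
  expect_identical(res$p_perm, res2$p_perm)
  expect_error(morans_i(rep(1, 36), W), "constant")
})

test_that("OLS reproduces exact fits and the normal equations", {
  set.seed(2)
  X <- cbind(a = rnorm(10), b = rnorm(10))
  y_exact <- 2 + 3 * X[, "a"] - X[, "b"]
  f <- fit_ols(y_exact, X)
  expect_equal(unname(f$coefficients), c(2, 3, -1), tolerance = 1e-9)
  expect_equal(max(abs(f$residuals)), 0, tolerance = 1e-9)
  # intercept-only model estimates the mean
  y <- rnorm(10)
  expect_equal(unname(fit_ols(y, matrix(numeric(0), 10, 0))$coefficients),
               mean(y))
  # independent solve of the normal equations on a noisy fixture
  yn <- y_exact + rnorm(10)
  f2 <- fit_ols(yn, X)
  Xd <- cbind(1, X)
  expect_equal(unname(f2$coefficients),
               unname(solve(t(Xd) %*% Xd, t(Xd) %*% yn)[, 1]),
               tolerance = 1e-9)
  # residuals orthogonal to the design columns
  expect_lt(max(abs(t(Xd) %*% f2$residuals)), 1e-8)
  expect_error(fit_ols(yn, cbind(X, X[, 1])), "rank deficient")
})

test_that("zero weights collapse the lag model onto OLS", {
  set.seed(4)
  X <- cbind(a = rnorm(30))
  y <- 1 + 2 * X[, 1] + rnorm(30)
  W0 <- structure(list(n = 30, ids = as.character(1:30),
                       neighbours = rep(list(integer(0)), 30),
                       weights = rep(list(numeric(0)), 30)),
                  class = "spatial_weights")
  lag <- fit_spatial_lag(y, X, W0)
  ols <- fit_ols(y, X)
  expect_equal(lag$rho, 0)
  expect_equal(lag$coefficients, ols$coefficients, tolerance = 1e-8)
  expect_equal(lag$loglik, ols$loglik, tolerance = 1e-8)
  expect_equal(lag$lr_stat, 0)
})

test_that("SAR simulation hits its closed-form limits", {
  set.seed(6)
  pts <- cbind(runif(25), runif(25))
  W <- build_knn_weights(pts, k = 3)
  X <- cbind(1, rnorm(25))
  y0 <- simulate_sar(W, 0, c(1, 2), 1, X, seed = 11)
  eps <- with(list(), {set.seed(11); rnorm(25, 0, 1)})
  expect_equal(y0, as.vector(X %*% c(1, 2)) + eps)
  expect_equal(simulate_sar(W, 0, c(0, 0), 0, X, seed = 1), rep(0, 25))
  expect_error(simulate_sar(W, 1.5, c(0, 0), 1, X), "rho")
})

test_that("stronger spatial dependence raises sample Moran's I", {
  set.seed(8)
  pts <- cbind(runif(100, 0, 10), runif(100, 0, 10))
  W <- build_knn_weights(pts, k = 6)
  X <- matrix(rnorm(100), 100, 1)
  y_lo <- simulate_sar(W, 0, c(0.5), 1, X, seed = 21)
  y_hi <- simulate_sar(W, 0.7, c(0.5), 1, X, seed = 21)
  expect_gt(brute_moran(y_hi, W), brute_moran(y_lo, W))
})

test_that("the lag fit recovers rho and beta on simulated data", {
  set.seed(10)
  pts <- cbind(runif(300, 0, 100), runif(300, 0, 100))
  W <- build_knn_weights(pts, k = 8)
  X <- cbind(x1 = rnorm(300), x2 = rnorm(300))
  rhos <- betas <- numeric(10)
  for (i in 1:10) {
    y <- simulate_sar(W, 0.5, c(0.5, 1, -0.5), 1, cbind(1, X), seed = 300 + i)
    f <- fit_spatial_lag(y, X, W, se = (i == 1))
    rhos[i] <- f$rho
    betas[i] <- f$coefficients[["x1"]]
    expect_gte(f$lr_stat, 0)
    expect_lt(f$aic, f$ols$aic)  # lag model should win under rho = 0.5
  }
  expect_lt(abs(mean(rhos) - 0.5), 0.1)
  expect_lt(abs(mean(betas) - 1), 0.1)
})

test_that("lag-model standard errors are asymptotically calibrated", {
  # z-scores of a true null coefficient should look standard normal
  set.seed(12)
  pts <- cbind(runif(200, 0, 50), runif(200, 0, 50))
  W <- build_knn_weights(pts, k = 8)
  X <- cbind(x1 = rnorm(200), x0 = rnorm(200))  # x0 has zero true effect
  z <- vapply(1:30, function(i) {
    y <- simulate_sar(W, 0.4, c(0.5, 1, 0), 1, cbind(1, X), seed = 600 + i)
    f <- fit_spatial_lag(y, X, W)
    f$z[["x0"]]
  }, numeric(1))
  expect_lt(abs(mean(z)), 0.6)
  expect_gt(sd(z), 0.6)
  expect_lt(sd(z), 1.6)
})
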