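test_that("vif_screen keeps orthogonal columns and collapses duplicates", {
  X <- withr::with_seed(1, tibble::as_tibble(
    matrix(rnorm(300 * 4), 300, 4, dimnames = list(NULL, paste0("v", 1:4)))))
  expect_identical(vif_screen(X), paste0("v", 1:4))
  X$v5 <- X$v1                      # exact duplicate
  kept <- vif_screen(X)
  expect_identical(length(intersect(c("v1", "v5"), kept)), 1L)
  X$v6 <- 1
  expect_error(vif_screen(X), "v6")
})

test_that("the 47-column collinear construction screens down to its 13-core", {
  cp <- simulate_collinear_predictors(seed = 4)
  expect_identical(ncol(cp$data), 47L)
  kept <- vif_screen(cp$data)
  expect_identical(sort(kept), sort(cp$core))
})

test_that("standardization centres and scales to 1e-9", {
  X <- withr::with_seed(2, tibble::tibble(cell = 0:99, a = rnorm(100, 5, 3),
                                          b = runif(100)))
  Z <- standardize_predictors(X)
  expect_identical(Z$cell, X$cell)
  expect_lt(abs(mean(Z$a)), 1e-9)
  expect_lt(abs(stats::sd(Z$a) - 1), 1e-9)
})

test_that("knn weights symmetrize by union and row-standardize", {
  # 3 collinear equidistant points, k = 1
  w <- knn_weights(cbind(x = c(0, 1, 2), y = 0), 1)
  expect_identical(sum(w$B[2, ]), 2L)    # middle gains both ends
  expect_equal(rowSums(w$W), rep(1, 3))
  expect_true(isSymmetric(w$B + 0))
  # regular grid, k = 4 -> interior neighbours are the rook cells
  g <- grid_spec(0, 0, 1, 10, 10)
  ctr <- cell_centers(g)
  w4 <- knn_weights(ctr[, c("x", "y")], 4)
  i <- which(ctr$cell == 44)             # interior cell (row 4, col 4)
  expect_setequal(ctr$cell[w4$B[i, ] == 1], c(34, 54, 43, 45))
  expect_error(knn_weights(cbind(c(0, 0), c(1, 1)), 1), "duplicate")
})

test_that("lambda = 0 reproduces OLS exactly and noiseless fits are perfect", {
  sim <- simulate_sar_surface(synthetic_scenario(n_rows = 8, n_cols = 8,
                                                 lambda = 0.4, seed = 5))
  X <- as.matrix(sim$data[, c("x1", "x2")])
  f0 <- fit_sar_error(sim$data$y, X, sim$W, fixed_lambda = 0)
  ols <- stats::coef(stats::lm(sim$data$y ~ X))
  expect_equal(unname(f0$coefficients), unname(ols), tolerance = 1e-10)
  # y exactly X beta: residuals ~ 0, GR2 at its ceiling
  y_pure <- as.numeric(X %*% c(1, -0.5))
  fp <- fit_sar_error(y_pure, X, sim$W, fixed_lambda = 0)
  expect_lt(max(abs(fp$residuals)), 1e-9)
  expect_gt(fp$GR2, 0.99)
  # intercept-only non-spatial fit defines the GR2 zero point
  f00 <- fit_sar_error(sim$data$y, NULL, sim$W, fixed_lambda = 0)
  expect_equal(f00$GR2, 0, tolerance = 1e-12)
})

test_that("SAR-error ML recovers planted beta and lambda", {
  sc <- synthetic_scenario(n_rows = 12, n_cols = 12, beta = c(1, -0.5),
                           lambda = 0.6, sigma = 1, seed = 31)
  est <- t(vapply(1:12, function(r) {
    sim <- simulate_sar_surface(sc, seed_offset = r)
    f <- fit_sar_error(sim$data$y, sim$data[, c("x1", "x2")], sim$W)
    c(f$coefficients[["x1"]], f$coefficients[["x2"]], f$lambda)
  }, numeric(3)))
  mu <- colMeans(est)
  se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  expect_true(all(abs(mu - c(1, -0.5, 0.6)) <= 3 * se + 0.05))
  expect_true(all(abs(est[, 3]) < 1))
})

test_that("AICc exceeds AIC and converges to it as n grows", {
  sc <- synthetic_scenario(n_rows = 8, n_cols = 8, seed = 7)
  sim <- simulate_sar_surface(sc)
  f <- fit_sar_error(sim$data$y, sim$data[, c("x1", "x2")], sim$W)
  expect_gt(f$AICc, f$AIC)
  sc2 <- synthetic_scenario(n_rows = 18, n_cols = 18, seed = 7)
  sim2 <- simulate_sar_surface(sc2)
  f2 <- fit_sar_error(sim2$data$y, sim2$data[, c("x1", "x2")], sim2$W)
  expect_lt(f2$AICc - f2$AIC, f$AICc - f$AIC)
})

test_that("select_sar returns the AICc winner with small-k tie break", {
  sc <- synthetic_scenario(n_rows = 8, n_cols = 8, lambda = 0.5, seed = 13)
  sim <- simulate_sar_surface(sc)
  one <- select_sar(sim$data$y, sim$data[, c("x1", "x2")], sim$coords,
                    k_candidates = 4)
  expect_identical(one$k, 4L)
  best <- select_sar(sim$data$y, sim$data[, c("x1", "x2")], sim$coords,
                     k_candidates = c(2, 4, 6))
  path <- attr(best, "aicc_path")
  expect_identical(best$AICc, min(path$AICc))
  tie <- select_sar(sim$data$y, sim$data[, c("x1", "x2")], sim$coords,
                    k_candidates = c(3, 3))
  expect_identical(tie$k, 3L)
})

test_that("correlograms sit near -1/(n-1) for noise and decay for smooth fields", {
  sc <- synthetic_scenario(n_rows = 10, n_cols = 10, seed = 17)
  ctr <- cell_centers(sc$grid)
  iid <- withr::with_seed(18, rnorm(100))
  cg <- moran_correlogram(iid, ctr)
  expect_identical(nrow(cg), 10L)
  expect_true(all(abs(cg$moran_i[cg$n_pairs > 100] - (-1 / 99)) < 0.15))
  # strongly autocorrelated field: first class above last
  sim <- simulate_sar_surface(sc)
  field <- sim$data$x1
  cg2 <- moran_correlogram(field, ctr)
  expect_gt(cg2$moran_i[1], cg2$moran_i[max(which(!is.na(cg2$moran_i)))])
  # single class equals global Moran's I with distance-band weights
  cg1 <- moran_correlogram(field, ctr, n_classes = 1)
  d <- as.matrix(stats::dist(ctr[, c("x", "y")]))
  w <- d > 0
  zc <- field - mean(field)
  manual <- 100 / sum(w) * sum(w * outer(zc, zc)) / sum(zc^2)
  expect_equal(cg1$moran_i, manual, tolerance = 1e-12)
  expect_error(moran_correlogram(rep(1, 100), ctr), "constant")
})
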