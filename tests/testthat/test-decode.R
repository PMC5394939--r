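test_that("likelihood-table rows peak at the grid point nearest the RF centre", {
  grid <- decoding_grid()
  fits <- fits_from_truth(make_population(
    mu_x = c(-2.21, 0.61), mu_y = c(1.32, -0.47), sigma = c(0.8, 1.4)))
  tab <- build_likelihood_table(fits, grid)
  for (j in 1:2) {
    peak <- which.max(tab$pred[j, ])
    nearest <- which.min((grid$positions$gx - fits$mu_x[j])^2 +
                           (grid$positions$gy - fits$mu_y[j])^2)
    expect_equal(peak, nearest)
  }
  # zero-gain voxel: constant row at baseline
  f0 <- fits_from_truth(make_population(0, 0, 1, c1 = 0, c0 = 0.4))
  t0 <- build_likelihood_table(f0, grid)
  expect_equal(as.vector(t0$pred), rep(0.4, ncol(t0$pred)))
  expect_error(build_likelihood_table(fits[0, ], grid), "no voxels")
})

test_that("raster tables converge to the radial quadrature as pixels shrink", {
  grid <- decoding_grid(n_x = 12, n_y = 12)
  fits <- fits_from_truth(make_population(
    mu_x = c(0.4, -1.1), mu_y = c(-0.3, 0.9), sigma = c(0.9, 1.7)))
  t_rad <- build_likelihood_table(fits, grid)
  # exact quadrature reference at every grid point
  t_exact <- t_rad$pred
  for (j in 1:2) {
    d <- sqrt((grid$positions$gx - fits$mu_x[j])^2 +
                (grid$positions$gy - fits$mu_y[j])^2)
    t_exact[j, ] <- vapply(d, function(dd) {
      prfdecode:::gauss_disk_overlap_exact(dd, fits$sigma[j], 0.8)
    }, numeric(1))
  }
  scale <- max(abs(t_exact))
  expect_lt(max(abs(t_rad$pred - t_exact)) / scale, 0.005)
  err <- vapply(c(0.1, 0.05, 0.025), function(ps) {
    t_ras <- build_likelihood_table(fits, grid,
                                    stimulus_spec(pixel_size = ps), "raster")
    max(abs(t_ras$pred - t_exact)) / scale
  }, numeric(1))
  expect_true(all(diff(err) < 0))  # refinement converges on the quadrature
  expect_lt(err[3], 0.01)
})

test_that("ML decoding equals an exhaustive brute-force likelihood scan", {
  grid <- decoding_grid()  # full 3600-point grid
  set.seed(20)
  fits <- fits_from_truth(make_population(
    mu_x = runif(30, -3, 3), mu_y = runif(30, -3, 3),
    sigma = runif(30, 0.5, 2.5), sigma_noise = runif(30, 0.5, 2)))
  tab <- build_likelihood_table(fits, grid)
  for (case in 1:50) {
    act <- tab$pred[, sample(ncol(tab$pred), 1)] +
      rnorm(30, sd = fits$sigma_noise)
    got <- decode_ml(act, tab)
    # oracle: full Gaussian log density summed per grid point
    ll <- vapply(seq_len(ncol(tab$pred)), function(g) {
      sum(dnorm(act, tab$pred[, g], fits$sigma_noise, log = TRUE))
    }, numeric(1))
    g <- which.max(ll)
    expect_equal(unname(got), c(grid$positions$gx[g], grid$positions$gy[g]))
  }
})

test_that("noiseless population activity decodes to the exact grid point", {
  grid <- decoding_grid()
  set.seed(21)
  fits <- fits_from_truth(make_population(
    mu_x = runif(50, -3, 3), mu_y = runif(50, -3, 3),
    sigma = runif(50, 0.6, 2), sigma_noise = 1))
  tab <- build_likelihood_table(fits, grid)
  for (g in sample(ncol(tab$pred), 5)) {
    got <- decode_ml(tab$pred[, g], tab)
    expect_equal(unname(got),
                 c(grid$positions$gx[g], grid$positions$gy[g]))
  }
})

test_that("decoding is invariant to voxel order and rejects bad input", {
  grid <- decoding_grid(n_x = 20, n_y = 20)
  set.seed(22)
  fits <- fits_from_truth(make_population(
    mu_x = runif(15, -2, 2), mu_y = runif(15, -2, 2), sigma = 1,
    sigma_noise = runif(15, 0.5, 1.5)))
  tab <- build_likelihood_table(fits, grid)
  act <- rnorm(15)
  perm <- sample(15)
  tab_p <- build_likelihood_table(fits[perm, ], grid)
  expect_equal(decode_ml(act, tab), decode_ml(act[perm], tab_p))
  expect_error(decode_ml(c(act, 0), tab), "voxel count")
  act[3] <- NA
  expect_error(decode_ml(act, tab), "non-finite")
})

test_that("the SVR kernel has unit diagonal and is duplication-invariant", {
  set.seed(23)
  A <- matrix(rnorm(20 * 8), 20, 8)
  k <- kernlab::rbfdot(sigma = 1 / ncol(A))
  K <- kernlab::kernelMatrix(k, A)
  expect_equal(unname(diag(K)), rep(1, 20))
  # doubling voxels doubles ||r1 - r2||^2 and N: kernel unchanged
  A2 <- cbind(A, A)
  K2 <- kernlab::kernelMatrix(kernlab::rbfdot(sigma = 1 / ncol(A2)), A2)
  expect_equal(unname(K2), unname(K), tolerance = 1e-12)
})

test_that("SVR fits low-noise data well and predicts deterministically", {
  vols <- make_volumes(n_runs = 1, schedule = short_schedule(4), seed = 24)
  pop <- uniform_population(40, sigma = 1.2, sigma_noise = 0.1, seed = 25)
  A <- series_matrix(simulate_responses(pop, vols, seed = 26))$amplitudes
  mod <- train_svr(A, vols)
  pred <- predict_svr(mod, A)
  expect_gt(cor(pred$pred_x, vols$sx), 0.9)
  expect_gt(cor(pred$pred_y, vols$sy), 0.9)
  expect_equal(pred, mod$train_pred)
  # smoothness: an epsilon amplitude change moves predictions by O(epsilon)
  A2 <- A; A2[1, 1] <- A2[1, 1] + 1e-4
  pred2 <- predict_svr(mod, A2)
  expect_lt(max(abs(pred2$pred_x - pred$pred_x)), 1e-3)
  expect_error(predict_svr(mod, A[, 1:10]), "voxel count")
})

test_that("constant targets yield a constant SVR prediction", {
  set.seed(27)
  A <- matrix(rnorm(30 * 5), 30, 5)
  vols <- tibble::tibble(volume = 1:30, run = 1L, sx = 1.5, sy = -0.5)
  mod <- train_svr(A, vols)
  pred <- predict_svr(mod, matrix(rnorm(10 * 5), 10, 5))
  expect_equal(pred$pred_x, rep(1.5, 10))
  expect_equal(pred$pred_y, rep(-0.5, 10))
})

test_that("cross-validation predicts every volume exactly once", {
  vols <- make_volumes(n_runs = 3, schedule = short_schedule(2), seed = 28)
  pop <- uniform_population(30, sigma = 1.2, sigma_noise = 0.4, seed = 29)
  ser <- simulate_responses(pop, vols, seed = 30)
  dec <- cross_validate(ser, vols, method = "ml")
  expect_equal(dec$volume, vols$volume)
  expect_equal(dec$true_x, vols$sx)
  expect_equal(attr(dec, "skipped_runs"), integer(0))
  expect_equal(length(attr(dec, "n_selected")), 3)
  # low noise: held-out decoding should track the truth well
  acc <- prediction_accuracy(dec)
  expect_gt(acc$r_horizontal, 0.9)
  expect_gt(acc$r_vertical, 0.9)
})

test_that("folds with no selected voxels are skipped with a warning", {
  vols <- make_volumes(n_runs = 2, seed = 31)
  nt <- nrow(vols)
  ser <- tibble::tibble(
    voxel = rep(1:5, each = nt), volume = rep(vols$volume, 5),
    run = rep(vols$run, 5), amplitude = 1  # constant: fit r is 0 everywhere
  )
  expect_warning(   # both folds warn: catch one per expectation
    expect_warning(dec <- cross_validate(ser, vols, method = "ml"),
                   "no voxels selected"),
    "no voxels selected")
  expect_equal(nrow(dec), 0)
})
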