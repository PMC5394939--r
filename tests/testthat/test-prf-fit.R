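test_that("log-likelihood matches the Gaussian formula and its stationarity", {
  vols <- make_volumes(n_runs = 1, seed = 1)[1:10, ]
  p <- prf_params(mu_x = 0, mu_y = 0, sigma = 1, sigma_noise = 1)
  pop <- make_population(0, 0, 1, sigma_noise = 1)
  rhat <- as.vector(predict_response(pop, vols))
  # zero residuals, T = 10, sigma_noise = 1 -> -5 log(2 pi)
  expect_equal(log_likelihood(p, rhat, vols), -5 * log(2 * pi),
               tolerance = 1e-12)

  # argmax over sigma_noise alone is the RMS residual
  set.seed(2)
  obs <- rhat + rnorm(10, sd = 0.5)
  rms <- sqrt(mean((obs - rhat)^2))
  best <- optimize(function(sn) {
    pp <- p; pp$sigma_noise <- sn
    log_likelihood(pp, obs, vols)
  }, c(0.01, 5), maximum = TRUE)
  expect_equal(best$maximum, rms, tolerance = 1e-4)

  # shifting both the data and the baseline leaves the value unchanged
  p2 <- p; p2$c0 <- p$c0 + 3.3
  expect_equal(log_likelihood(p, obs, vols),
               log_likelihood(p2, obs + 3.3, vols), tolerance = 1e-10)

  p3 <- p; p3$sigma_noise <- -1
  expect_error(log_likelihood(p3, obs, vols), "positive")
})

test_that("near-noiseless voxels are recovered to tight tolerance", {
  vols <- make_volumes(n_runs = 2, schedule = short_schedule(2), seed = 3)
  pop <- make_population(
    mu_x = c(0.31, -1.67, 2.2), mu_y = c(-0.42, 1.05, -2.6),
    sigma = c(0.6, 1.1, 2.3), sigma_noise = 0.01
  )
  ser <- simulate_responses(pop, vols, seed = 4)
  fits <- fit_prf_population(ser, vols)
  err <- sqrt((fits$mu_x - pop$mu_x)^2 + (fits$mu_y - pop$mu_y)^2)
  expect_lt(max(err), 0.1)
  expect_lt(max(abs(fits$sigma / pop$sigma - 1)), 0.05)
  # fitted likelihood at least as high as at the generating parameters
  sm <- series_matrix(ser)
  for (j in seq_len(nrow(pop))) {
    truth <- prf_params(c0 = pop$c0[j], c1 = pop$c1[j],
                        mu_x = pop$mu_x[j], mu_y = pop$mu_y[j],
                        sigma = pop$sigma[j],
                        sigma_noise = max(pop$sigma_noise[j], 1e-3))
    ll_truth <- log_likelihood(truth, sm$amplitudes[, j], vols)
    expect_gte(fits$log_lik[j] + 1e-6, ll_truth)
  }
})

test_that("profiled fitting agrees with brute-force likelihood maximisation", {
  # oracle: dense (mu, sigma) grid with lm() profiling of c0/c1 per point
  vols <- make_volumes(n_runs = 1, schedule = short_schedule(2), seed = 5)
  lk <- prfdecode:::overlap_lookup(0.8)
  set.seed(6)
  for (case in 1:5) {
    truth <- make_population(runif(1, -2, 2), runif(1, -2, 2),
                             runif(1, 0.5, 2), sigma_noise = 0.3)
    ser <- simulate_responses(truth, vols, seed = 600 + case)
    y <- series_matrix(ser)$amplitudes[, 1]
    fit <- fit_prf(y, vols)

    mu_grid <- seq(-3.8, 3.8, by = 0.15)
    sig_grid <- exp(seq(log(0.3), log(3), length.out = 15))
    best <- Inf
    best_mu <- c(NA, NA)
    for (sg in sig_grid) {
      prof <- prfdecode:::overlap_profile(sg, 0.8, lk)
      for (mx in mu_grid) for (my in mu_grid) {
        d <- sqrt((vols$sx - mx)^2 + (vols$sy - my)^2)
        m <- prfdecode:::profile_at(d, prof)
        rss <- sum(lm.fit(cbind(1, m), y)$residuals^2)
        if (rss < best) {
          best <- rss
          best_mu <- c(mx, my)
        }
      }
    }
    T <- length(y)
    ll_oracle <- -T / 2 * (log(2 * pi * best / T) + 1)
    # the optimiser must do at least as well as the dense scan
    expect_gte(fit$log_lik, ll_oracle - 0.01 * abs(ll_oracle))
    d <- sqrt((fit$params$mu_x - best_mu[1])^2 +
                (fit$params$mu_y - best_mu[2])^2)
    expect_lt(d, 0.25)
  }
})

test_that("fit quality is invariant to affine transforms of the amplitudes", {
  vols <- make_volumes(n_runs = 1, schedule = short_schedule(2), seed = 7)
  pop <- make_population(0.5, -0.5, 1, sigma_noise = 1)
  y <- series_matrix(simulate_responses(pop, vols, seed = 8))$amplitudes[, 1]
  f1 <- fit_prf(y, vols)
  f2 <- fit_prf(3.7 * y - 11, vols)
  expect_equal(f1$fit_r, f2$fit_r, tolerance = 1e-4)
})

test_that("pure-noise voxels rarely clear the selection threshold", {
  # full-length training set: in-sample inflation is mild at T = 960
  vols <- make_volumes(n_runs = 2, schedule = run_schedule(), seed = 9)
  nt <- nrow(vols)
  set.seed(10)
  n_null <- 40
  ser <- tibble::tibble(
    voxel = rep(seq_len(n_null), each = nt),
    volume = rep(vols$volume, n_null),
    run = rep(vols$run, n_null),
    amplitude = rnorm(n_null * nt)
  )
  fits <- fit_prf_population(ser, vols)
  # optimisation inflates in-sample fit r above 0, but seldom past 0.2
  expect_gt(mean(fits$fit_r > 0), 0.5)
  expect_lt(mean(fits$fit_r > 0.2), 0.2)
})

test_that("constant series yield a flagged, unselected fit", {
  vols <- make_volumes(n_runs = 1, seed = 11)
  ser <- tibble::tibble(voxel = 1L, volume = vols$volume, run = vols$run,
                        amplitude = 2)
  fits <- fit_prf_population(ser, vols)
  expect_equal(fits$fit_r, 0)
  expect_false(fits$selected)
})

test_that("selection applies the centre-field and strict fit-r rules", {
  base <- tibble::tibble(
    voxel = 1:4, c0 = 0, c1 = 1,
    mu_x = c(0, 4.0, 0, 3.7), mu_y = c(0, 0, 0, -3.7),
    sigma = 1, sigma_noise = 1, log_lik = 0,
    fit_r = c(0.25, 0.25, 0.2, 0.21),
    center_in_field = NA, selected = NA
  )
  sel <- select_voxels(base)
  expect_equal(sel$voxel, c(1L, 4L))   # 2: outside field; 3: r not > 0.2
  expect_warning(
    select_voxels(dplyr::mutate(base, fit_r = 0.1)), "no voxels"
  )
})

test_that("eccentricity-size curve bins correctly and tracks the generator", {
  flat <- fits_from_truth(make_population(
    mu_x = rep(0.3, 5), mu_y = rep(0.4, 5), sigma = 1))
  curve <- eccentricity_size_curve(flat)
  expect_equal(nrow(curve), 1)
  expect_equal(curve$bin, 1L)
  expect_equal(curve$mean_sigma, 1)

  p <- area_presets()[3, ]
  p$n_voxels <- 500L
  pop <- sample_population(p, seed = 12)
  curve2 <- eccentricity_size_curve(fits_from_truth(pop))
  expect_true(all(diff(curve2$mean_sigma) > 0))  # positive size slope
})
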