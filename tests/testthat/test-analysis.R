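test_that("prediction accuracy handles identity, mirroring, and noise attenuation", {
  vols <- make_volumes(n_runs = 1, seed = 1)
  perfect <- tibble::tibble(volume = vols$volume, true_x = vols$sx,
                            true_y = vols$sy, pred_x = vols$sx,
                            pred_y = vols$sy)
  acc <- prediction_accuracy(perfect)
  expect_equal(acc$r_horizontal, 1)
  expect_equal(acc$r_vertical, 1)

  mirrored <- dplyr::mutate(perfect, pred_x = -pred_x)
  acc2 <- prediction_accuracy(mirrored)
  expect_equal(acc2$r_horizontal, -1)
  expect_equal(acc2$r_vertical, 1)

  # prediction = truth + noise with SD equal to the truth's SD -> r ~ 1/sqrt(2)
  sched <- run_schedule()
  tr <- simulate_trajectory(trajectory_config(seed = 2),
                            3 * frames_per_run(sched))
  v3 <- frames_to_volumes(tr, sched, 3)
  set.seed(3)
  noisy <- tibble::tibble(
    volume = v3$volume, true_x = v3$sx, true_y = v3$sy,
    pred_x = v3$sx + rnorm(1440, sd = sd(v3$sx)),
    pred_y = v3$sy + rnorm(1440, sd = sd(v3$sy))
  )
  acc3 <- prediction_accuracy(noisy)
  expect_equal(acc3$r_horizontal, 1 / sqrt(2), tolerance = 0.03 * sqrt(2))
  expect_equal(acc3$r_vertical, 1 / sqrt(2), tolerance = 0.03 * sqrt(2))

  flat <- dplyr::mutate(perfect, pred_x = 0)
  expect_warning(acc4 <- prediction_accuracy(flat), "zero variance")
  expect_true(is.na(acc4$r_horizontal))
})

test_that("fisher z matches atanh, is antisymmetric, and rejects |r| >= 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.75), 0.97296, tolerance = 1e-5)
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1), "< 1")
})

test_that("centre spread uses the sample SD per axis", {
  fits <- fits_from_truth(make_population(mu_x = c(-1, 1), mu_y = c(0, 0),
                                          sigma = 1))
  cs <- center_spread(fits)
  expect_equal(cs$sd_x, sqrt(2))
  expect_equal(cs$sd_y, 0)
  expect_error(center_spread(fits[1, ]), "at least 2")

  same <- fits_from_truth(make_population(mu_x = rep(0.7, 4),
                                          mu_y = rep(-0.2, 4), sigma = 1))
  expect_equal(unlist(center_spread(same)[, 1:2]), c(sd_x = 0, sd_y = 0))

  pop <- sample_population(area_presets(500)[6, ], seed = 4)
  cs2 <- center_spread(fits_from_truth(pop))
  expect_lt(cs2$sd_y, cs2$sd_x)
})

test_that("distance-exclusion at threshold 0 equals the plain decode and decays", {
  vols <- make_volumes(n_runs = 1, schedule = short_schedule(2), seed = 5)
  pop <- uniform_population(60, sigma = 1, sigma_noise = 0.5, seed = 6)
  ser <- simulate_responses(pop, vols, seed = 7)
  fits <- fits_from_truth(pop)
  grid <- decoding_grid()
  curve <- distance_exclusion_curve(fits, ser, vols,
                                    thresholds = seq(0, 3, 0.5), grid = grid)

  tab <- build_likelihood_table(fits, grid)
  plain <- decode_ml(series_matrix(ser)$amplitudes, tab)
  r0 <- cor(vols$sx, plain$pred_x)
  expect_equal(curve$r_horizontal[1], r0, tolerance = 1e-10)
  expect_equal(curve$n_skipped[1], 0)
  # excluding informative voxels cannot help much: broad downward trend
  expect_lt(min(curve$r_horizontal, na.rm = TRUE), r0)
})

test_that("a threshold beyond every centre-stimulus distance skips all volumes", {
  vols <- make_volumes(n_runs = 1, seed = 8)
  pop <- make_population(mu_x = c(0, 1), mu_y = c(0, -1), sigma = 1,
                         sigma_noise = 0.5)
  ser <- simulate_responses(pop, vols, seed = 9)
  curve <- distance_exclusion_curve(fits_from_truth(pop), ser, vols,
                                    thresholds = c(0, 50))
  expect_equal(curve$n_volumes[2], 0)
  expect_true(is.na(curve$r_horizontal[2]))
})

test_that("exponential decay fitting recovers exact curves and is equivariant", {
  d <- seq(0, 4, by = 0.5)
  y <- 0.7 * exp(-d / 1.5) + 0.05
  fit <- fit_exponential_decay(tibble::tibble(threshold = d, accuracy = y))
  expect_equal(fit$tau, 1.5, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.7, tolerance = 1e-6)
  expect_equal(fit$baseline, 0.05, tolerance = 1e-6)
  expect_true(fit$identifiable)

  fit2 <- fit_exponential_decay(tibble::tibble(threshold = d,
                                               accuracy = 2 * y))
  expect_equal(fit2$tau, fit$tau, tolerance = 1e-5)
  expect_equal(fit2$amplitude, 2 * fit$amplitude, tolerance = 1e-5)
  expect_equal(fit2$baseline, 2 * fit$baseline, tolerance = 1e-5)

  flat <- fit_exponential_decay(tibble::tibble(threshold = d,
                                               accuracy = rep(0.4, 9)))
  expect_false(flat$identifiable)
  expect_lt(abs(flat$amplitude), 0.01)
})

test_that("one-way F matches hand-computed sums of squares and aov", {
  st <- one_way_f(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(st$f_statistic, 13.5)
  expect_equal(st$df_between, 1L)
  expect_equal(st$df_within, 4L)

  expect_equal(one_way_f(list(c(2, 2), c(2, 2), c(2, 2)))$f_statistic, 0)

  # random data: agree with an aov() oracle to 1e-8
  set.seed(10)
  for (i in 1:5) {
    g <- lapply(1:4, function(k) rnorm(5, mean = k / 10))
    st2 <- one_way_f(g)
    df <- data.frame(value = unlist(g),
                     grp = factor(rep(1:4, each = 5)))
    aa <- summary(aov(value ~ grp, df))[[1]]
    expect_equal(st2$f_statistic, aa$`F value`[1], tolerance = 1e-8)
    expect_equal(st2$p_value, aa$`Pr(>F)`[1], tolerance = 1e-8)
  }
})

test_that("paired t handles identical, constant-shift, and hand-computed cases", {
  st <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(st$t_statistic, 0)
  expect_true(st$zero_variance)

  st2 <- paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4))  # differences all 1
  expect_true(st2$zero_variance)
  expect_equal(st2$t_statistic, Inf)

  # differences {1, 2, 3}: t = mean / (sd / sqrt(3)) = 2 sqrt(3)
  st3 <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(st3$t_statistic, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(st3$df, 2L)
  ht <- t.test(c(2, 4, 6), c(1, 2, 3), paired = TRUE)
  expect_equal(st3$p_value, ht$p.value, tolerance = 1e-12)
})

test_that("the subject CI is the t interval and contains the mean", {
  ci <- ci_across_subjects(c(0.3, 0.3, 0.3))
  expect_equal(ci$ci_low, 0.3)
  expect_equal(ci$ci_high, 0.3)

  ci2 <- ci_across_subjects(c(0, 1))
  half <- qt(0.975, 1) * sd(c(0, 1)) / sqrt(2)
  expect_equal(ci2$ci_low, 0.5 - half, tolerance = 1e-12)
  expect_equal(ci2$ci_high, 0.5 + half, tolerance = 1e-12)
  expect_true(ci2$ci_low <= ci2$mean && ci2$mean <= ci2$ci_high)
  expect_error(ci_across_subjects(0.5), "at least 2")
})

test_that("subsampling all selected voxels once equals the full decode", {
  vols <- make_volumes(n_runs = 2, schedule = short_schedule(2), seed = 11)
  pop <- uniform_population(25, sigma = 1.2, sigma_noise = 0.15, seed = 12,
                            half_width = 2.5)
  ser <- simulate_responses(pop, vols, seed = 13)
  full <- prediction_accuracy(cross_validate(ser, vols, method = "ml"))
  # all folds select all 25 voxels at this noise
  sub <- subsample_accuracy(ser, vols, n_voxels = 25, n_repeats = 1,
                            seed = 14)
  expect_equal(sub$r_horizontal, full$r_horizontal, tolerance = 1e-10)
  expect_equal(sub$r_vertical, full$r_vertical, tolerance = 1e-10)

  # determinism under a fixed seed
  s1 <- subsample_accuracy(ser, vols, n_voxels = 10, n_repeats = 3, seed = 15)
  s2 <- subsample_accuracy(ser, vols, n_voxels = 10, n_repeats = 3, seed = 15)
  expect_identical(s1$r_horizontal, s2$r_horizontal)
  expect_error(subsample_accuracy(ser, vols, n_voxels = 26, n_repeats = 1,
                                  seed = 16), "selected voxels")

  # more voxels should not hurt on average
  s_small <- subsample_accuracy(ser, vols, n_voxels = 5, n_repeats = 5,
                                seed = 17)
  s_big <- subsample_accuracy(ser, vols, n_voxels = 20, n_repeats = 5,
                              seed = 18)
  expect_gt(s_big$r_horizontal, s_small$r_horizontal - 0.02)
})
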