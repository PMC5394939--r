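# Shared fixture builders.  Everything is generated in code at test time;
# sizes are kept small so the whole suite runs on one CPU in minutes.

# short schedule: one 60-s block per run -> 30 volumes/run at TR 2
short_schedule <- function(n_blocks = 1, block_duration_s = 60) {
  run_schedule(n_blocks = n_blocks, block_duration_s = block_duration_s)
}

make_volumes <- function(n_runs = 2, schedule = short_schedule(), seed = 1,
                         sigma_stim = 0.1) {
  tc <- trajectory_config(seed = seed, sigma_stim = sigma_stim)
  traj <- simulate_trajectory(tc, n_runs * frames_per_run(schedule))
  frames_to_volumes(traj, schedule, n_runs)
}

# hand-built population tibble with explicit parameters
make_population <- function(mu_x, mu_y, sigma, sigma_noise = 0.5,
                            c0 = 0, c1 = 1, area = "test") {
  n <- length(mu_x)
  tibble::tibble(
    voxel = seq_len(n), area = area, c0 = c0, c1 = c1,
    mu_x = mu_x, mu_y = mu_y, sigma = sigma, sigma_noise = sigma_noise
  )
}

# population with centers uniform over the span field
uniform_population <- function(n, sigma, sigma_noise, seed,
                               half_width = 3.8) {
  withr::with_seed(seed, {
    make_population(
      mu_x = stats::runif(n, -half_width, half_width),
      mu_y = stats::runif(n, -half_width, half_width),
      sigma = rep(sigma, length.out = n),
      sigma_noise = sigma_noise
    )
  })
}

# fits tibble straight from ground truth (bypasses fitting) for decoder tests
fits_from_truth <- function(population) {
  out <- dplyr::mutate(population, log_lik = NA_real_, fit_r = 1,
                       center_in_field = TRUE, selected = TRUE)
  class(out) <- c("prf_fits", class(tibble::tibble()))
  out
}
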