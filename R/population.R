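#' Construct a set of pRF parameters
#'
#' The six constants of the Gaussian population receptive field model: the
#' observed amplitude at volume t is
#' `r(t) ~ N(c0 + c1 * overlap(mu, sigma; s(t)), sigma_noise^2)` where the
#' overlap is the integral of the Gaussian kernel over the stimulus disk.
#'
#' @param c0 Baseline amplitude.
#' @param c1 Gain amplitude.
#' @param mu_x,mu_y Receptive-field centre, degrees.
#' @param sigma Receptive-field size (Gaussian SD), degrees; must be > 0.
#' @param sigma_noise Response noise SD, amplitude units; must be > 0.
#' @return A named list of class `"prf_params"`.
#' @export
prf_params <- function(c0 = 0, c1 = 1, mu_x = 0, mu_y = 0, sigma = 1,
                       sigma_noise = 1) {
  stopifnot(sigma > 0, sigma_noise > 0)
  structure(
    list(c0 = c0, c1 = c1, mu_x = mu_x, mu_y = mu_y, sigma = sigma,
         sigma_noise = sigma_noise),
    class = "prf_params"
  )
}

#' Area presets emulating six visual areas
#'
#' Returns generative presets for synthetic voxel populations modelled on the
#' ventral-stream hierarchy V1 through FFA: receptive-field size (and its
#' scaling with eccentricity) increases from the V1-like to the FFA-like
#' preset, while the vertical scatter of RF centres narrows sharply for the
#' LOC-like and FFA-like presets (their `center_sd_y` is a quarter of
#' `center_sd_x`), emulating the anisotropic centre distributions of higher
#' ventral areas.  Numeric values are the package's own choices, a
#' qualitative emulation of the real-area statistics rather than a
#' reproduction.
#'
#' Noise SDs are calibrated so that, under the default trajectory and run
#' schedule, median model-fit correlations land near 0.2-0.3, the working
#' regime of real voxel fits.
#'
#' @param n_voxels Voxels per area (default 200, within the range of
#'   per-area selected voxel counts in real data).
#' @return A tibble with one row per preset, ordered V1like to FFAlike:
#'   columns `area`, `n_voxels`, `center_sd_x`, `center_sd_y`,
#'   `size_intercept`, `size_slope`, `size_floor`, `noise_sd`,
#'   `baseline_c0`, `gain_c1`.
#' @export
area_presets <- function(n_voxels = 200) {
  tibble::tibble(
    area = c("V1like", "V2like", "V3like", "V4like", "LOClike", "FFAlike"),
    n_voxels = as.integer(n_voxels),
    center_sd_x = c(1.8, 1.8, 1.8, 1.8, 1.8, 1.8),
    center_sd_y = c(1.8, 1.7, 1.7, 1.6, 0.45, 0.45),
    size_intercept = c(0.6, 0.7, 0.8, 1.0, 1.4, 1.8),
    size_slope = c(0.15, 0.18, 0.22, 0.28, 0.35, 0.40),
    size_floor = 0.2,
    noise_sd = c(1.6, 1.8, 2.0, 2.3, 2.5, 2.4),
    baseline_c0 = 0,
    gain_c1 = 1
  )
}

#' Sample a ground-truth voxel population from a preset
#'
#' RF centres are drawn from a centred 2-D Gaussian with axis SDs
#' (`center_sd_x`, `center_sd_y`), truncated by rejection to the span field
#' (|mu| <= `span_half_width` on both axes, the 7.6 x 7.6 degree field the
#' stimulus can span).  RF size follows the linear eccentricity scaling
#' `sigma = max(size_floor, size_intercept + size_slope * eccentricity)`.
#'
#' @param preset A one-row data frame as produced by [area_presets()] (or a
#'   named list with the same fields).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param span_half_width Truncation half-width for RF centres, degrees.
#' @return A tibble of class `"voxel_population"`: columns `voxel`, `area`,
#'   `c0`, `c1`, `mu_x`, `mu_y`, `sigma`, `sigma_noise`.
#' @export
sample_population <- function(preset, seed = NULL, span_half_width = 3.8) {
  preset <- as.list(preset)
  n <- as.integer(preset$n_voxels)
  stopifnot(n >= 1, preset$center_sd_x >= 0, preset$center_sd_y >= 0,
            preset$size_floor > 0)

  draw <- function() {
    mu <- matrix(NA_real_, n, 2)
    need <- seq_len(n)
    while (length(need) > 0) {
      mu[need, 1] <- stats::rnorm(length(need), 0, preset$center_sd_x)
      mu[need, 2] <- stats::rnorm(length(need), 0, preset$center_sd_y)
      need <- which(pmax(abs(mu[, 1]), abs(mu[, 2])) > span_half_width)
    }
    mu
  }
  mu <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  ecc <- sqrt(mu[, 1]^2 + mu[, 2]^2)
  out <- tibble::tibble(
    voxel = seq_len(n),
    area = preset$area %||% "custom",
    c0 = preset$baseline_c0,
    c1 = preset$gain_c1,
    mu_x = mu[, 1],
    mu_y = mu[, 2],
    sigma = pmax(preset$size_floor,
                 preset$size_intercept + preset$size_slope * ecc),
    sigma_noise = preset$noise_sd
  )
  class(out) <- c("voxel_population", class(out))
  out
}

#' Noiseless forward-model responses of a population
#'
#' @param population A [sample_population()] tibble (or any tibble with
#'   columns `voxel`, `c0`, `c1`, `mu_x`, `mu_y`, `sigma`).
#' @param volumes A [frames_to_volumes()] tibble.
#' @param spec A [stimulus_spec()].
#' @return A matrix of predicted amplitudes, volumes x voxels.
#' @export
predict_response <- function(population, volumes, spec = stimulus_spec()) {
  lk <- overlap_lookup(spec$stimulus_radius)
  S <- cbind(volumes$sx, volumes$sy)
  out <- matrix(NA_real_, nrow(S), nrow(population))
  for (j in seq_len(nrow(population))) {
    d <- sqrt((S[, 1] - population$mu_x[j])^2 +
              (S[, 2] - population$mu_y[j])^2)
    out[, j] <- population$c0[j] +
      population$c1[j] * overlap_at(d, population$sigma[j], lk)
  }
  out
}

#' Simulate noisy voxel responses to a stimulus sequence
#'
#' Amplitude of voxel n at volume t is the Gaussian-RF / stimulus-disk
#' overlap plus i.i.d. Gaussian noise with that voxel's `sigma_noise`
#' (independent across voxels and volumes).  Optionally a per-voxel linear
#' drift is injected (slope in amplitude units per volume, within run) to
#' exercise detrending.
#'
#' @param population A [sample_population()] tibble.
#' @param volumes A [frames_to_volumes()] tibble.
#' @param spec A [stimulus_spec()].
#' @param seed Integer seed for the response noise.
#' @param drift_sd SD of the per-voxel drift slope, amplitude units per
#'   volume (default 0 = no drift).
#' @return A tibble of class `"voxel_series"`, long format with columns
#'   `voxel`, `volume`, `run`, `amplitude`; the generating population is
#'   attached as attribute `"population"`.
#' @export
simulate_responses <- function(population, volumes, spec = stimulus_spec(),
                               seed = NULL, drift_sd = 0) {
  stopifnot(nrow(population) >= 1, nrow(volumes) >= 1)
  mean_amp <- predict_response(population, volumes, spec)
  nv <- nrow(population)
  nt <- nrow(volumes)

  draw <- function() {
    amp <- mean_amp +
      matrix(stats::rnorm(nt * nv), nt, nv) *
        rep(population$sigma_noise, each = nt)
    if (drift_sd > 0) {
      slopes <- stats::rnorm(nv, 0, drift_sd)
      tt <- stats::ave(seq_len(nt), volumes$run, FUN = seq_along)
      amp <- amp + outer(tt, slopes)
    }
    amp
  }
  amp <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  out <- tibble::tibble(
    voxel = rep(population$voxel, each = nt),
    volume = rep(volumes$volume, nv),
    run = rep(volumes$run, nv),
    amplitude = as.vector(amp)
  )
  class(out) <- c("voxel_series", class(out))
  attr(out, "population") <- population
  out
}

#' Linearly detrend voxel time series within runs
#'
#' Per voxel and per run, the least-squares line over the volume index is
#' subtracted, leaving each voxel's per-run mean at zero.  Runs with fewer
#' than 3 volumes are left unchanged with a warning.
#'
#' @param series A long [simulate_responses()] tibble (columns `voxel`,
#'   `volume`, `run`, `amplitude`).
#' @return The detrended series, same shape and class.
#' @export
linear_detrend <- function(series) {
  stopifnot(all(c("voxel", "volume", "run", "amplitude") %in% names(series)))
  short <- series |>
    dplyr::distinct(.data$run, .data$volume) |>
    dplyr::count(.data$run, name = "n_vol") |>
    dplyr::filter(.data$n_vol < 3)
  if (nrow(short) > 0) {
    warning(sprintf("run(s) %s have fewer than 3 volumes; left untrended",
                    paste(short$run, collapse = ", ")), call. = FALSE)
  }
  pop <- attr(series, "population")
  out <- series |>
    dplyr::group_by(.data$voxel, .data$run) |>
    dplyr::mutate(amplitude = detrend_vec(.data$amplitude)) |>
    dplyr::ungroup()
  class(out) <- c("voxel_series", class(tibble::tibble()))
  attr(out, "population") <- pop
  out
}

detrend_vec <- function(y) {
  n <- length(y)
  if (n < 3) return(y)
  t <- seq_len(n)
  tc <- t - mean(t)
  b <- sum(tc * y) / sum(tc^2)
  y - (mean(y) + b * tc)
}

#' Spread voxel series into a volumes-by-voxels amplitude matrix
#'
#' @param series A long `voxel_series` tibble.
#' @return A list with `amplitudes` (matrix, volumes x voxels), `voxel`
#'   (column ids), `volume` and `run` (row labels).
#' @export
series_matrix <- function(series) {
  vox <- sort(unique(series$voxel))
  s <- dplyr::arrange(series, .data$voxel, .data$volume)
  nt <- nrow(s) / length(vox)
  stopifnot(nt == as.integer(nt))
  amp <- matrix(s$amplitude, nrow = nt, ncol = length(vox))
  first <- s[seq_len(nt), ]
  list(amplitudes = amp, voxel = vox, volume = first$volume, run = first$run)
}
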