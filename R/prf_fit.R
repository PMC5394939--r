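#' Options controlling pRF model fitting and voxel selection
#'
#' Maximum-likelihood fitting is initialised on a regular grid of candidate
#' centres and sizes to avoid local optima: for every grid point the
#' amplitude baseline `c0` and gain `c1` are profiled out by linear least
#' squares and the noise SD by the RMS residual (jointly the exact ML
#' solution given the RF shape), and the best grid point seeds a Nelder-Mead
#' simplex refinement over (mu_x, mu_y, log sigma).  Optimising log sigma
#' enforces positivity without an upper bound.
#'
#' @param mu_grid_spacing Spacing of the centre initialisation grid, degrees.
#' @param sigma_grid Candidate RF sizes for initialisation, degrees.
#' @param max_iterations Simplex iteration cap.
#' @param convergence_tol Relative convergence tolerance of the simplex.
#' @param r_threshold Fit-quality threshold; voxels are selected when their
#'   fit correlation strictly exceeds it (default 0.2).
#' @param span_half_width Half-width of the field RF centres may occupy
#'   (default 3.8 degrees: the span field of the stimulus).
#' @return A list of class `"fit_options"`.
#' @export
fit_options <- function(mu_grid_spacing = 0.5,
                        sigma_grid = c(0.25, 0.5, 1, 2, 4),
                        max_iterations = 300,
                        convergence_tol = 1e-8,
                        r_threshold = 0.2,
                        span_half_width = 3.8) {
  stopifnot(mu_grid_spacing > 0, length(sigma_grid) >= 1, all(sigma_grid > 0),
            r_threshold > -1, r_threshold < 1, span_half_width > 0)
  structure(
    list(mu_grid_spacing = mu_grid_spacing, sigma_grid = sigma_grid,
         max_iterations = max_iterations, convergence_tol = convergence_tol,
         r_threshold = r_threshold, span_half_width = span_half_width),
    class = "fit_options"
  )
}

#' Log-likelihood of a voxel time series under the pRF model
#'
#' Evaluates `-T/2 * log(2 pi sigma_noise^2) - sum((r(t) - rhat(t))^2) /
#' (2 sigma_noise^2)` with `rhat` the Gaussian-RF / stimulus overlap model.
#'
#' @param params A [prf_params()] (requires `sigma_noise > 0`).
#' @param amplitudes Numeric vector of observed amplitudes, one per volume.
#' @param volumes A [frames_to_volumes()] tibble of the same length.
#' @param spec A [stimulus_spec()].
#' @return The scalar log-likelihood.
#' @export
log_likelihood <- function(params, amplitudes, volumes,
                           spec = stimulus_spec()) {
  params <- as.list(params)
  if (!is.numeric(params$sigma_noise) || params$sigma_noise <= 0) {
    stop("`sigma_noise` must be positive", call. = FALSE)
  }
  stopifnot(length(amplitudes) == nrow(volumes), length(amplitudes) >= 1)
  pop <- tibble::tibble(c0 = params$c0, c1 = params$c1, mu_x = params$mu_x,
                        mu_y = params$mu_y, sigma = params$sigma)
  rhat <- as.vector(predict_response(pop, volumes, spec))
  T <- length(amplitudes)
  -T / 2 * log(2 * pi * params$sigma_noise^2) -
    sum((amplitudes - rhat)^2) / (2 * params$sigma_noise^2)
}

# profiled residual sum of squares given a model shape m (unit-gain overlap):
# OLS of r on (1, m); returns list(rss, c0, c1)
profile_ls <- function(r, m, ss_r, r_mean) {
  mm <- mean(m)
  mc <- m - mm
  ssm <- sum(mc^2)
  if (ssm < 1e-12) {
    return(list(rss = ss_r, c0 = r_mean, c1 = 0))
  }
  b <- sum(mc * (r - r_mean)) / ssm
  rss <- max(ss_r - b^2 * ssm, 0)
  list(rss = rss, c0 = r_mean - b * mm, c1 = b)
}

#' Fit Gaussian pRF models to every voxel of a series
#'
#' Runs the grid-initialised profiled maximum-likelihood fit (see
#' [fit_options()]) for each voxel of a long amplitude series and applies
#' the centre-in-field rule.  Fit quality is the Pearson correlation between
#' observed and fitted amplitudes on the training data (in-sample).
#'
#' @param series A long `voxel_series` tibble (columns `voxel`, `volume`,
#'   `run`, `amplitude`) covering exactly the volumes in `volumes`.
#' @param volumes A [frames_to_volumes()] tibble.
#' @param options A [fit_options()].
#' @param spec A [stimulus_spec()].
#' @return A tibble of class `"prf_fits"` with one row per voxel: `voxel`,
#'   `c0`, `c1`, `mu_x`, `mu_y`, `sigma`, `sigma_noise`, `log_lik`, `fit_r`,
#'   `center_in_field`, `selected`.
#' @export
fit_prf_population <- function(series, volumes, options = fit_options(),
                               spec = stimulus_spec()) {
  sm <- series_matrix(series)
  stopifnot(nrow(sm$amplitudes) == nrow(volumes))
  A <- sm$amplitudes
  T <- nrow(A)
  if (T < 10) stop("need at least 10 volumes to fit", call. = FALSE)
  S <- cbind(volumes$sx, volumes$sy)
  lk <- overlap_lookup(spec$stimulus_radius)

  hw <- options$span_half_width
  mu_seq <- seq(-hw + options$mu_grid_spacing / 2,
                hw - options$mu_grid_spacing / 2,
                by = options$mu_grid_spacing)
  grid <- expand.grid(mx = mu_seq, my = mu_seq)
  D <- sqrt(outer(S[, 1], grid$mx, `-`)^2 + outer(S[, 2], grid$my, `-`)^2)

  nv <- ncol(A)
  a_mean <- colMeans(A)
  Ac <- sweep(A, 2, a_mean)
  ss_r <- colSums(Ac^2)

  # grid stage, vectorised across voxels: for each candidate sigma build the
  # model matrix over all centres once, then score all voxels by profiled LS
  best_rss <- rep(Inf, nv)
  best_mu <- matrix(0, nv, 2)
  best_sig <- rep(options$sigma_grid[1], nv)
  for (sg in options$sigma_grid) {
    prof <- overlap_profile(sg, spec$stimulus_radius, lk)
    M <- matrix(profile_at(as.vector(D), prof), nrow = T)
    Mc <- sweep(M, 2, colMeans(M))
    ssm <- colSums(Mc^2)
    ssm[ssm < 1e-12] <- NA_real_
    Bnum <- crossprod(Mc, Ac)                     # candidates x voxels
    rss <- sweep(-(Bnum^2) / ssm, 2, ss_r, `+`)   # rss per candidate/voxel
    rss[is.na(rss)] <- Inf
    cand <- apply(rss, 2, which.min)
    cand_rss <- rss[cbind(cand, seq_len(nv))]
    upd <- cand_rss < best_rss
    if (any(upd)) {
      best_rss[upd] <- cand_rss[upd]
      best_mu[upd, ] <- cbind(grid$mx[cand[upd]], grid$my[cand[upd]])
      best_sig[upd] <- sg
    }
  }

  res <- vector("list", nv)
  for (j in seq_len(nv)) {
    r <- A[, j]
    if (ss_r[j] < 1e-12) {
      res[[j]] <- tibble::tibble(
        voxel = sm$voxel[j], c0 = a_mean[j], c1 = 0, mu_x = NA_real_,
        mu_y = NA_real_, sigma = NA_real_, sigma_noise = 1e-8,
        log_lik = NA_real_, fit_r = 0, center_in_field = FALSE,
        selected = FALSE
      )
      next
    }
    obj <- function(th) {
      d <- sqrt((S[, 1] - th[1])^2 + (S[, 2] - th[2])^2)
      m <- overlap_at(d, exp(th[3]), lk)
      pl <- profile_ls(r, m, ss_r[j], a_mean[j])
      T / 2 * log(max(pl$rss, 1e-300) / T)
    }
    th0 <- c(best_mu[j, ], log(best_sig[j]))
    opt <- stats::optim(
      th0, obj, method = "Nelder-Mead",
      control = list(maxit = options$max_iterations,
                     reltol = options$convergence_tol)
    )
    th <- if (opt$value <= obj(th0)) opt$par else th0
    d <- sqrt((S[, 1] - th[1])^2 + (S[, 2] - th[2])^2)
    m <- overlap_at(d, exp(th[3]), lk)
    pl <- profile_ls(r, m, ss_r[j], a_mean[j])
    sn <- sqrt(max(pl$rss, 1e-300) / T)
    fitted <- pl$c0 + pl$c1 * m
    fr <- if (stats::sd(fitted) < 1e-12) 0 else stats::cor(r, fitted)
    cif <- abs(th[1]) <= hw && abs(th[2]) <= hw
    res[[j]] <- tibble::tibble(
      voxel = sm$voxel[j], c0 = pl$c0, c1 = pl$c1, mu_x = th[1],
      mu_y = th[2], sigma = exp(th[3]), sigma_noise = sn,
      log_lik = -T / 2 * (log(2 * pi * sn^2) + 1),
      fit_r = fr, center_in_field = cif,
      selected = cif && fr > options$r_threshold
    )
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("prf_fits", class(out))
  out
}

#' Fit the pRF model to a single voxel time series
#'
#' @param amplitudes Numeric vector of observed amplitudes (one per volume).
#' @param volumes A [frames_to_volumes()] tibble of matching length.
#' @param options A [fit_options()].
#' @param spec A [stimulus_spec()].
#' @return An object of class `"prf_fit"`: the fitted [prf_params()], plus
#'   `fit_r`, `log_lik`, `center_in_field`, `selected`.  Constant series
#'   yield `fit_r = 0` and `selected = FALSE`.
#' @export
fit_prf <- function(amplitudes, volumes, options = fit_options(),
                    spec = stimulus_spec()) {
  stopifnot(length(amplitudes) == nrow(volumes))
  series <- tibble::tibble(voxel = 1L, volume = volumes$volume,
                           run = volumes$run, amplitude = amplitudes)
  row <- fit_prf_population(series, volumes, options, spec)
  structure(
    list(
      params = prf_params(
        c0 = row$c0, c1 = row$c1,
        mu_x = ifelse(is.na(row$mu_x), 0, row$mu_x),
        mu_y = ifelse(is.na(row$mu_y), 0, row$mu_y),
        sigma = ifelse(is.na(row$sigma), 1, row$sigma),
        sigma_noise = max(row$sigma_noise, 1e-8)
      ),
      fit_r = row$fit_r, log_lik = row$log_lik,
      center_in_field = row$center_in_field, selected = row$selected,
      n_volumes = nrow(volumes)
    ),
    class = "prf_fit"
  )
}

#' @export
print.prf_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<prf_fit> center (%.2f, %.2f) deg, sigma %.2f deg, fit r = %.3f%s\n",
    p$mu_x, p$mu_y, p$sigma, x$fit_r,
    if (isTRUE(x$selected)) " [selected]" else ""
  ))
  invisible(x)
}

#' Apply the voxel-selection rules to a table of fits
#'
#' A voxel is retained when its estimated RF centre lies inside the span
#' field (|mu_x| and |mu_y| both <= `span_half_width`) and its fit
#' correlation strictly exceeds `r_threshold`.
#'
#' @param fits A `prf_fits` tibble from [fit_prf_population()].
#' @param options A [fit_options()] supplying the threshold and field width.
#' @return The selected subset (same columns, `selected` recomputed).  An
#'   empty survivor set is returned with a warning; downstream decoders
#'   reject it.
#' @export
select_voxels <- function(fits, options = fit_options()) {
  stopifnot(nrow(fits) >= 1)
  flagged <- fits |>
    dplyr::mutate(
      center_in_field = !is.na(.data$mu_x) & !is.na(.data$mu_y) &
        abs(.data$mu_x) <= options$span_half_width &
        abs(.data$mu_y) <= options$span_half_width,
      selected = .data$center_in_field & .data$fit_r > options$r_threshold
    )
  out <- dplyr::filter(flagged, .data$selected)
  if (nrow(out) == 0) {
    warning("no voxels survive selection", call. = FALSE)
  }
  class(out) <- c("prf_fits", class(tibble::tibble()))
  out
}

#' Mean receptive-field size by eccentricity bin
#'
#' Eccentricity of each RF centre (`sqrt(mu_x^2 + mu_y^2)`) is binned into
#' `n_bins` levels of width `bin_width` starting at zero, and the mean fitted
#' sigma per non-empty bin is returned.
#'
#' @param fits A (selected) `prf_fits` tibble.
#' @param bin_width Bin width in degrees (default 1).
#' @param n_bins Number of bins (default 5).
#' @return A tibble with `bin` (index), `ecc_lo`, `ecc_hi`, `mean_sigma`,
#'   `n_voxels`.
#' @export
eccentricity_size_curve <- function(fits, bin_width = 1, n_bins = 5) {
  stopifnot(bin_width > 0, n_bins >= 1)
  fits |>
    dplyr::mutate(ecc = sqrt(.data$mu_x^2 + .data$mu_y^2),
                  bin = 1L + as.integer(.data$ecc / bin_width)) |>
    dplyr::filter(.data$bin <= n_bins) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_sigma = mean(.data$sigma),
                     n_voxels = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(ecc_lo = (.data$bin - 1) * bin_width,
                  ecc_hi = .data$bin * bin_width) |>
    dplyr::select("bin", "ecc_lo", "ecc_hi", "mean_sigma", "n_voxels")
}
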