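#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single-voxel pRF fit
#'
#' @param x A `"prf_fit"` from [fit_prf()].
#' @param ... Unused.
#' @return A one-row tibble with the six fitted constants plus `fit_r`,
#'   `log_lik`, `center_in_field`, `selected`.
#' @method tidy prf_fit
#' @export
tidy.prf_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    c0 = p$c0, c1 = p$c1, mu_x = p$mu_x, mu_y = p$mu_y, sigma = p$sigma,
    sigma_noise = p$sigma_noise, fit_r = x$fit_r, log_lik = x$log_lik,
    center_in_field = x$center_in_field, selected = x$selected
  )
}

#' Glance at a single-voxel pRF fit
#'
#' @param x A `"prf_fit"`.
#' @param ... Unused.
#' @return A one-row tibble: `fit_r`, `log_lik`, `n_volumes`, `selected`.
#' @method glance prf_fit
#' @export
glance.prf_fit <- function(x, ...) {
  tibble::tibble(fit_r = x$fit_r, log_lik = x$log_lik,
                 n_volumes = x$n_volumes, selected = x$selected)
}

#' Tidy an exponential decay fit
#'
#' @param x A `"decay_fit"` from [fit_exponential_decay()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("tau", "amplitude", "baseline"),
    estimate = c(x$tau, x$amplitude, x$baseline)
  )
}

#' Glance at an exponential decay fit
#'
#' @param x A `"decay_fit"`.
#' @param ... Unused.
#' @return A one-row tibble: `tau`, `residual_sse`, `identifiable`,
#'   `n_points`.
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(tau = x$tau, residual_sse = x$residual_sse,
                 identifiable = x$identifiable, n_points = nrow(x$data))
}
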