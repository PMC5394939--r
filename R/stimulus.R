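#' Rendering specification for the binary stimulus image
#'
#' The stimulus indicator I(x, y; sx, sy) is 1 where the visual stimulus is
#' present and 0 elsewhere: a pixel is on iff its centre lies strictly within
#' `stimulus_radius` of the disk centre.  The render grid is symmetric about
#' the fixation origin with pixel centres at integer multiples of
#' `pixel_size`; x increases rightward, y upward, all in degrees of visual
#' angle.
#'
#' @param pixel_size Render-grid resolution, degrees (default 0.1, the
#'   granularity of the 60 x 60 decoding grid over the 6 degree field).
#' @param render_extent Half-width of the rendered field, degrees; must cover
#'   the span field (centre field half-width + stimulus radius, 3.8 by
#'   default).
#' @param stimulus_radius Disk radius, degrees.
#'
#' @return A list of class `"stimulus_spec"`.
#' @export
stimulus_spec <- function(pixel_size = 0.1, render_extent = 3.8,
                          stimulus_radius = 0.8) {
  stopifnot(pixel_size > 0, stimulus_radius > 0,
            render_extent >= stimulus_radius)
  structure(
    list(pixel_size = pixel_size, render_extent = render_extent,
         stimulus_radius = stimulus_radius),
    class = "stimulus_spec"
  )
}

pixel_centers <- function(spec) {
  k <- floor(spec$render_extent / spec$pixel_size + 1e-9)
  spec$pixel_size * seq.int(-k, k)
}

#' Render the binary stimulus image at one position
#'
#' @param position Length-2 numeric, the disk centre (sx, sy) in degrees.
#' @param spec A [stimulus_spec()].
#' @param radius Disk radius in degrees; defaults to the spec's radius.
#'
#' @return An object of class `"binary_image"`: a list with pixel-centre
#'   coordinate vectors `x`, `y` and a 0/1 matrix `values` where
#'   `values[i, j]` is the pixel at `(x[i], y[j])`.  Positions outside the
#'   field render a clipped disk.
#' @export
render_stimulus <- function(position, spec = stimulus_spec(),
                            radius = spec$stimulus_radius) {
  stopifnot(is.numeric(position), length(position) == 2, all(is.finite(position)))
  xs <- pixel_centers(spec)
  ys <- xs
  d2 <- outer((xs - position[1])^2, (ys - position[2])^2, `+`)
  structure(
    list(x = xs, y = ys,
         values = (d2 < radius^2) + 0L),
    class = "binary_image"
  )
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image> %d x %d pixels, %d on\n",
              length(x$x), length(x$y), sum(x$values)))
  invisible(x)
}

#' Tidy a binary stimulus image into pixel records
#'
#' @param x A `"binary_image"`.
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `value`.
#' @method tidy binary_image
#' @export
tidy.binary_image <- function(x, ...) {
  tibble::tibble(
    x = rep(x$x, times = length(x$y)),
    y = rep(x$y, each = length(x$x)),
    value = as.vector(x$values)
  )
}

#' Gaussian receptive field / stimulus overlap integral
#'
#' Evaluates the forward-model amplitude
#' `C0 + C1 * integral( exp(-((x - mu_x)^2 + (y - mu_y)^2) / (2 sigma^2)) *
#' I(x, y; sx, sy) dx dy)` by midpoint quadrature over the rendered binary
#' image: the Gaussian kernel is summed over on-pixels and scaled by the
#' pixel area.
#'
#' @param params A list or one-row data frame with fields `c0`, `c1`, `mu_x`,
#'   `mu_y`, `sigma` (see [prf_params()]).
#' @param position Length-2 numeric stimulus centre (sx, sy), degrees.
#' @param spec A [stimulus_spec()].
#' @return The scalar model amplitude.
#' @export
overlap_integral <- function(params, position, spec = stimulus_spec()) {
  params <- as.list(params)
  stopifnot(params$sigma > 0)
  img <- render_stimulus(position, spec)
  on <- which(img$values == 1L, arr.ind = TRUE)
  if (nrow(on) == 0) return(params$c0)
  dx <- img$x[on[, 1]] - params$mu_x
  dy <- img$y[on[, 2]] - params$mu_y
  g <- exp(-(dx^2 + dy^2) / (2 * params$sigma^2))
  params$c0 + params$c1 * sum(g) * spec$pixel_size^2
}

# ---- fast radial evaluation of the Gaussian/disk overlap -------------------
#
# The integral of an isotropic Gaussian of SD sigma centred a distance d from
# a disk of radius R is rotationally symmetric:
#   O(d) = 2*pi * int_0^R r * exp(-(r^2 + d^2) / (2 sigma^2)) * I0(r d / sigma^2) dr
# evaluated stably with the exponentially scaled Bessel I0:
#   integrand = r * exp(-(r - d)^2 / (2 sigma^2)) * I0_scaled(r d / sigma^2).
# Fitting and decoding evaluate this through a cached (d, log sigma) lookup
# table with bilinear interpolation; accuracy is commensurate with the
# raster quadrature of overlap_integral() (sub-percent, tested).

gauss_disk_overlap_exact <- function(d, sigma, radius, n_nodes = 80) {
  stopifnot(sigma > 0, radius > 0)
  gl <- pracma::gaussLegendre(n_nodes, 0, radius)
  r <- gl$x
  w <- gl$w
  # matrix: nodes x length(d)
  dm <- matrix(d, n_nodes, length(d), byrow = TRUE)
  rm <- matrix(r, n_nodes, length(d))
  integ <- rm * exp(-(rm - dm)^2 / (2 * sigma^2)) *
    besselI(rm * dm / sigma^2, 0, expon.scaled = TRUE)
  2 * pi * as.vector(crossprod(w, integ))
}

# closed form for a disk centred on the Gaussian (d = 0)
gauss_disk_overlap_centered <- function(sigma, radius) {
  2 * pi * sigma^2 * (1 - exp(-radius^2 / (2 * sigma^2)))
}

.prf_cache <- new.env(parent = emptyenv())

overlap_lookup <- function(radius,
                           sigma_range = c(0.05, 12),
                           n_sigma = 121,
                           d_max = 20,
                           d_step = 0.02) {
  key <- sprintf("lk_%.6f", radius)
  lk <- .prf_cache[[key]]
  if (!is.null(lk)) return(lk)
  d_grid <- seq(0, d_max, by = d_step)
  ls_grid <- seq(log(sigma_range[1]), log(sigma_range[2]), length.out = n_sigma)
  vals <- vapply(
    ls_grid,
    function(ls) gauss_disk_overlap_exact(d_grid, exp(ls), radius),
    numeric(length(d_grid))
  )
  lk <- list(radius = radius, d_grid = d_grid, d_step = d_step,
             ls_grid = ls_grid, values = vals)
  .prf_cache[[key]] <- lk
  lk
}

# bilinear interpolation of the overlap at arbitrary (d, sigma);
# d beyond the table falls back to the point-stimulus approximation
# pi R^2 exp(-d^2 / (2 sigma^2)); sigma is clamped into the table range.
overlap_at <- function(d, sigma, lookup) {
  ls <- min(max(log(sigma), lookup$ls_grid[1]),
            lookup$ls_grid[length(lookup$ls_grid)])
  js <- findInterval(ls, lookup$ls_grid, all.inside = TRUE)
  ws <- (ls - lookup$ls_grid[js]) /
    (lookup$ls_grid[js + 1] - lookup$ls_grid[js])

  out <- numeric(length(d))
  far <- d > lookup$d_grid[length(lookup$d_grid)]
  if (any(far)) {
    out[far] <- pi * lookup$radius^2 * exp(-d[far]^2 / (2 * sigma^2))
  }
  if (any(!far)) {
    dn <- d[!far]
    jd <- pmin(1L + as.integer(dn / lookup$d_step), length(lookup$d_grid) - 1L)
    wd <- dn / lookup$d_step - (jd - 1L)
    v <- lookup$values
    out[!far] <-
      (1 - wd) * ((1 - ws) * v[jd, js] + ws * v[jd, js + 1]) +
      wd * ((1 - ws) * v[jd + 1, js] + ws * v[jd + 1, js + 1])
  }
  out
}

# per-sigma radial profile interpolated in d only (no sigma interpolation);
# used where sigma is one of a small set of known values (grid stage,
# response generation by exact column).
overlap_profile <- function(sigma, radius, lookup = overlap_lookup(radius)) {
  prof <- gauss_disk_overlap_exact(lookup$d_grid, sigma, radius)
  list(d_grid = lookup$d_grid, d_step = lookup$d_step, sigma = sigma,
       radius = radius, values = prof)
}

profile_at <- function(d, profile) {
  out <- numeric(length(d))
  far <- d > profile$d_grid[length(profile$d_grid)]
  if (any(far)) {
    out[far] <- pi * profile$radius^2 * exp(-d[far]^2 / (2 * profile$sigma^2))
  }
  if (any(!far)) {
    dn <- d[!far]
    jd <- pmin(1L + as.integer(dn / profile$d_step),
               length(profile$d_grid) - 1L)
    wd <- dn / profile$d_step - (jd - 1L)
    out[!far] <- (1 - wd) * profile$values[jd] + wd * profile$values[jd + 1]
  }
  out
}
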