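#' Decoding grid over the stimulus centre field
#'
#' Candidate positions are the centres of an `n_x` by `n_y` lattice of cells
#' tiling the square centre field (the only region the stimulus centre can
#' occupy), in deterministic row-major order: x varies fastest, then y.
#'
#' @param n_x,n_y Grid resolution (default 60 x 60).
#' @param half_width Half-width of the centre field, degrees (default 3).
#' @return A list of class `"decoding_grid"` with `x`, `y` (axis centre
#'   coordinates) and `positions` (tibble `gx`, `gy` in grid order).
#' @export
decoding_grid <- function(n_x = 60, n_y = 60, half_width = 3) {
  stopifnot(n_x >= 1, n_y >= 1, half_width > 0)
  sx <- seq(-half_width + half_width / n_x, half_width - half_width / n_x,
            length.out = n_x)
  sy <- seq(-half_width + half_width / n_y, half_width - half_width / n_y,
            length.out = n_y)
  structure(
    list(n_x = n_x, n_y = n_y, half_width = half_width, x = sx, y = sy,
         positions = tibble::tibble(gx = rep(sx, times = n_y),
                                    gy = rep(sy, each = n_x))),
    class = "decoding_grid"
  )
}

#' Precompute per-voxel predicted amplitudes at every grid position
#'
#' Entry (n, g) is the noiseless forward-model amplitude of voxel n were the
#' stimulus centred at grid point g.  With `method = "radial"` (default) the
#' Gaussian/disk overlap is evaluated through the radial quadrature lookup;
#' `method = "raster"` sums the rendered binary image explicitly (slower;
#' the two agree to sub-percent, which a test asserts).
#'
#' @param fits A selected `prf_fits` tibble (at least one voxel).
#' @param grid A [decoding_grid()].
#' @param spec A [stimulus_spec()].
#' @param method `"radial"` or `"raster"`.
#' @return A list of class `"likelihood_table"`: `pred` (voxels x grid
#'   matrix), `weights` (1 / sigma_noise^2 per voxel), `fits`, `grid`.
#' @export
build_likelihood_table <- function(fits, grid = decoding_grid(),
                                   spec = stimulus_spec(),
                                   method = c("radial", "raster")) {
  method <- match.arg(method)
  if (nrow(fits) == 0) stop("no voxels to decode with", call. = FALSE)
  stopifnot(all(fits$sigma_noise > 0))
  G <- nrow(grid$positions)
  pred <- matrix(NA_real_, nrow(fits), G)
  if (method == "radial") {
    lk <- overlap_lookup(spec$stimulus_radius)
    for (j in seq_len(nrow(fits))) {
      d <- sqrt((grid$positions$gx - fits$mu_x[j])^2 +
                (grid$positions$gy - fits$mu_y[j])^2)
      pred[j, ] <- fits$c0[j] + fits$c1[j] * overlap_at(d, fits$sigma[j], lk)
    }
  } else {
    for (j in seq_len(nrow(fits))) {
      p <- list(c0 = fits$c0[j], c1 = fits$c1[j], mu_x = fits$mu_x[j],
                mu_y = fits$mu_y[j], sigma = fits$sigma[j])
      pred[j, ] <- vapply(
        seq_len(G),
        function(g) overlap_integral(
          p, c(grid$positions$gx[g], grid$positions$gy[g]), spec),
        numeric(1)
      )
    }
  }
  structure(
    list(pred = pred, weights = 1 / fits$sigma_noise^2, fits = fits,
         grid = grid),
    class = "likelihood_table"
  )
}

#' Maximum-likelihood position decoding on the grid
#'
#' Under independent Gaussian noise across voxels, the log-likelihood of a
#' population amplitude vector r at grid position g is (up to
#' position-independent constants) `-sum_n (r_n - pred_ng)^2 /
#' (2 sigma_noise_n^2)`; the grid point maximising it is returned.  Ties are
#' broken by the lowest grid index in the deterministic row-major ordering.
#'
#' @param activity Numeric vector of amplitudes (one per voxel of the table),
#'   or a volumes-by-voxels matrix for many volumes at once.
#' @param table A [build_likelihood_table()].
#' @return For a vector: a named numeric `c(pred_x, pred_y)`.  For a matrix:
#'   a tibble with `pred_x`, `pred_y` per row.
#' @export
decode_ml <- function(activity, table) {
  stopifnot(inherits(table, "likelihood_table"))
  one <- is.null(dim(activity))
  A <- if (one) matrix(activity, 1) else as.matrix(activity)
  if (ncol(A) != nrow(table$pred)) {
    stop("activity has wrong voxel count", call. = FALSE)
  }
  if (!all(is.finite(A))) stop("non-finite amplitudes", call. = FALSE)
  w <- table$weights
  P <- table$pred
  # -2 * loglik (up to constants): rowSums(w r^2) - 2 (r w) P + colSums(w P^2)
  cross <- (A * rep(w, each = nrow(A))) %*% P
  quad <- colSums(w * P^2)
  S <- sweep(-2 * cross, 2, quad, `+`)  # row-constant terms dropped
  g <- max.col(-S, ties.method = "first")
  px <- table$grid$positions$gx[g]
  py <- table$grid$positions$gy[g]
  if (one) c(pred_x = px, pred_y = py) else tibble::tibble(pred_x = px,
                                                           pred_y = py)
}

#' Train a kernel support-vector regression position decoder
#'
#' Trains one epsilon-insensitive SVR per axis on population amplitude
#' vectors with the Gaussian kernel `k(r1, r2) = exp(-||r1 - r2||^2 / N)`,
#' where N is the number of voxels (so the kernel is invariant to duplicating
#' the population).  Amplitudes are z-scored per voxel with training-set
#' statistics before entering the kernel.
#'
#' @param train_activity Volumes-by-voxels amplitude matrix.
#' @param train_positions A [frames_to_volumes()] tibble of matching length
#'   (columns `sx`, `sy` are the targets).
#' @param cost SVR regularisation constant C (default 1).
#' @param epsilon Insensitivity band (default 0.1).
#' @return An object of class `"svr_decoder"`.
#' @export
train_svr <- function(train_activity, train_positions, cost = 1,
                      epsilon = 0.1) {
  A <- as.matrix(train_activity)
  stopifnot(nrow(A) >= 2, ncol(A) >= 1, nrow(A) == nrow(train_positions))
  ctr <- colMeans(A)
  scl <- apply(A, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Z <- sweep(sweep(A, 2, ctr), 2, scl, `/`)
  N <- ncol(A)
  fit_axis <- function(y) {
    if (stats::sd(y) < 1e-12) {
      return(list(constant = mean(y)))
    }
    kernlab::ksvm(
      x = Z, y = y, type = "eps-svr", kernel = "rbfdot",
      kpar = list(sigma = 1 / N), C = cost, epsilon = epsilon,
      scaled = FALSE
    )
  }
  model <- structure(
    list(mx = fit_axis(train_positions$sx),
         my = fit_axis(train_positions$sy),
         center = ctr, scale = scl, n_voxels = N,
         cost = cost, epsilon = epsilon),
    class = "svr_decoder"
  )
  model$train_pred <- predict_svr(model, A)
  model
}

#' Predict stimulus positions with a trained SVR decoder
#'
#' Predictions are not clipped to the field.
#'
#' @param model A [train_svr()] decoder.
#' @param activity Volumes-by-voxels amplitude matrix (voxel count must match
#'   training).
#' @return A tibble with `pred_x`, `pred_y` per volume.
#' @export
predict_svr <- function(model, activity) {
  stopifnot(inherits(model, "svr_decoder"))
  A <- as.matrix(activity)
  if (ncol(A) != model$n_voxels) {
    stop("activity has wrong voxel count", call. = FALSE)
  }
  Z <- sweep(sweep(A, 2, model$center), 2, model$scale, `/`)
  ax <- function(m) {
    if (is.list(m)) rep(m$constant, nrow(Z))
    else as.vector(kernlab::predict(m, Z))
  }
  tibble::tibble(pred_x = ax(model$mx), pred_y = ax(model$my))
}

#' Leave-one-run-out cross-validated position decoding
#'
#' For each fold one run is held out; pRF models are fitted and voxels
#' selected on the remaining (training) runs only, the decoder (grid ML or
#' SVR; SVR uses the same ML-selected voxel set) is built on training data,
#' and positions are predicted for every volume of the held-out run.  Folds
#' are concatenated in original volume order.
#'
#' @param series A long `voxel_series` tibble.
#' @param volumes The matching [frames_to_volumes()] tibble (>= 2 runs).
#' @param method `"ml"` or `"svr"`.
#' @param fit_opts A [fit_options()].
#' @param grid A [decoding_grid()] (ML decoding).
#' @param spec A [stimulus_spec()].
#' @param cost,epsilon SVR hyperparameters.
#' @param detrend Detrend the series within runs before fitting/decoding.
#' @return A tibble of class `"decoded_trajectory"`: `volume`, `run`,
#'   `method`, `true_x`, `true_y`, `pred_x`, `pred_y`.  Folds in which no
#'   voxel survives selection are skipped with a warning and recorded in the
#'   `"skipped_runs"` attribute; per-fold selected-voxel counts are in
#'   attribute `"n_selected"`.
#' @export
cross_validate <- function(series, volumes, method = c("ml", "svr"),
                           fit_opts = fit_options(), grid = decoding_grid(),
                           spec = stimulus_spec(), cost = 1, epsilon = 0.1,
                           detrend = FALSE) {
  method <- match.arg(method)
  runs <- sort(unique(volumes$run))
  if (length(runs) < 2) stop("need at least 2 runs", call. = FALSE)
  if (detrend) series <- linear_detrend(series)
  sm <- series_matrix(series)
  stopifnot(nrow(sm$amplitudes) == nrow(volumes))

  skipped <- integer(0)
  n_sel <- stats::setNames(integer(length(runs)), runs)
  folds <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    test_run <- runs[i]
    tr <- volumes$run != test_run
    te <- !tr
    train_series <- dplyr::filter(series, .data$run != test_run)
    train_vol <- volumes[tr, ]
    fits <- fit_prf_population(train_series, train_vol, fit_opts, spec)
    sel <- suppressWarnings(select_voxels(fits, fit_opts))
    n_sel[i] <- nrow(sel)
    if (nrow(sel) == 0) {
      warning(sprintf("fold with test run %s: no voxels selected; skipped",
                      test_run), call. = FALSE)
      skipped <- c(skipped, test_run)
      next
    }
    keep <- match(sel$voxel, sm$voxel)
    A_te <- sm$amplitudes[te, keep, drop = FALSE]
    if (method == "ml") {
      tab <- build_likelihood_table(sel, grid, spec)
      pred <- decode_ml(A_te, tab)
    } else {
      A_tr <- sm$amplitudes[tr, keep, drop = FALSE]
      mod <- train_svr(A_tr, train_vol, cost = cost, epsilon = epsilon)
      pred <- predict_svr(mod, A_te)
    }
    folds[[i]] <- tibble::tibble(
      volume = volumes$volume[te], run = volumes$run[te],
      method = toupper(method),
      true_x = volumes$sx[te], true_y = volumes$sy[te],
      pred_x = pred$pred_x, pred_y = pred$pred_y
    )
  }
  empty <- tibble::tibble(
    volume = integer(0), run = integer(0), method = character(0),
    true_x = numeric(0), true_y = numeric(0),
    pred_x = numeric(0), pred_y = numeric(0)
  )
  out <- dplyr::arrange(dplyr::bind_rows(c(list(empty), folds)),
                        .data$volume)
  class(out) <- c("decoded_trajectory", class(out))
  attr(out, "skipped_runs") <- skipped
  attr(out, "n_selected") <- n_sel
  out
}
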