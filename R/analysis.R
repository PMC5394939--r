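#' Per-axis prediction accuracy of a decoded trajectory
#'
#' Accuracy is the Pearson correlation between true and predicted coordinates
#' per axis, pooled over all predicted volumes.
#'
#' @param decoded A `decoded_trajectory` tibble (carries `true_x`, `true_y`,
#'   `pred_x`, `pred_y`), or any tibble with those columns.
#' @param truth Optional [frames_to_volumes()] tibble to take true positions
#'   from instead (matched on `volume`).
#' @return A one-row tibble: `r_horizontal`, `r_vertical`, `n_volumes`.
#'   Zero-variance predictions give `NA` with a warning.
#' @export
prediction_accuracy <- function(decoded, truth = NULL) {
  if (!is.null(truth)) {
    m <- match(decoded$volume, truth$volume)
    decoded <- dplyr::mutate(decoded, true_x = truth$sx[m],
                             true_y = truth$sy[m])
  }
  stopifnot(nrow(decoded) >= 3)
  safe_cor <- function(a, b, axis) {
    if (stats::sd(b) < 1e-12 || stats::sd(a) < 1e-12) {
      warning(sprintf("zero variance on the %s axis; accuracy undefined",
                      axis), call. = FALSE)
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  tibble::tibble(
    r_horizontal = safe_cor(decoded$true_x, decoded$pred_x, "horizontal"),
    r_vertical = safe_cor(decoded$true_y, decoded$pred_y, "vertical"),
    n_volumes = nrow(decoded)
  )
}

#' Fisher z-transform of a correlation coefficient
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, variance-stabilising for
#' group statistics on correlations.
#'
#' @param r Correlation(s), strictly inside (-1, 1).
#' @return The transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.na(r) & abs(r) >= 1)) {
    stop("|r| must be < 1 for the Fisher z-transform", call. = FALSE)
  }
  atanh(r)
}

#' Spread of receptive-field centres
#'
#' Sample standard deviation (n - 1 denominator) of the fitted centre
#' coordinates across selected voxels, per axis.
#'
#' @param fits A (selected) `prf_fits` tibble with >= 2 voxels.
#' @return A one-row tibble: `sd_x`, `sd_y`, `n_voxels`.
#' @export
center_spread <- function(fits) {
  if (nrow(fits) < 2) stop("need at least 2 voxels", call. = FALSE)
  tibble::tibble(
    sd_x = stats::sd(fits$mu_x),
    sd_y = stats::sd(fits$mu_y),
    n_voxels = nrow(fits)
  )
}

#' Decoding accuracy with a fixed number of randomly selected voxels
#'
#' Repeats the leave-one-run-out ML decode drawing `n_voxels` voxels
#' uniformly without replacement from each fold's selected set, and averages
#' the per-axis accuracies over repeats.  pRF fits are computed once per fold
#' and shared across repeats (only the decoded subset changes).
#'
#' @param series A long `voxel_series` tibble.
#' @param volumes The matching volume series (>= 2 runs).
#' @param n_voxels Voxels drawn per repeat (must not exceed the smallest
#'   fold's selected count).
#' @param n_repeats Number of random draws (default 100).
#' @param seed Integer seed for the draws.
#' @param fit_opts,grid,spec See [cross_validate()].
#' @return A one-row tibble: `n_voxels`, `n_repeats`, `r_horizontal`,
#'   `r_vertical` (means over repeats); per-repeat accuracies in attribute
#'   `"repeats"`.
#' @export
subsample_accuracy <- function(series, volumes, n_voxels, n_repeats = 100,
                               seed = NULL, fit_opts = fit_options(),
                               grid = decoding_grid(),
                               spec = stimulus_spec()) {
  runs <- sort(unique(volumes$run))
  stopifnot(length(runs) >= 2, n_voxels >= 1, n_repeats >= 1)
  sm <- series_matrix(series)

  fold_data <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    test_run <- runs[i]
    tr <- volumes$run != test_run
    fits <- fit_prf_population(dplyr::filter(series, .data$run != test_run),
                               volumes[tr, ], fit_opts, spec)
    sel <- suppressWarnings(select_voxels(fits, fit_opts))
    if (nrow(sel) < n_voxels) {
      stop(sprintf(
        "fold with test run %s has only %d selected voxels (< %d requested)",
        test_run, nrow(sel), n_voxels), call. = FALSE)
    }
    fold_data[[i]] <- list(sel = sel, te = !tr)
  }

  run_repeat <- function(k) {
    folds <- lapply(seq_along(runs), function(i) {
      fd <- fold_data[[i]]
      pick <- sort(sample.int(nrow(fd$sel), n_voxels))
      sub <- fd$sel[pick, ]
      tab <- build_likelihood_table(sub, grid, spec)
      keep <- match(sub$voxel, sm$voxel)
      pred <- decode_ml(sm$amplitudes[fd$te, keep, drop = FALSE], tab)
      tibble::tibble(volume = volumes$volume[fd$te],
                     true_x = volumes$sx[fd$te], true_y = volumes$sy[fd$te],
                     pred_x = pred$pred_x, pred_y = pred$pred_y)
    })
    acc <- prediction_accuracy(dplyr::bind_rows(folds))
    dplyr::mutate(acc, repeat_id = k)
  }
  go <- function() dplyr::bind_rows(lapply(seq_len(n_repeats), run_repeat))
  reps <- if (is.null(seed)) go() else withr::with_seed(seed, go())

  out <- tibble::tibble(
    n_voxels = n_voxels, n_repeats = n_repeats,
    r_horizontal = mean(reps$r_horizontal),
    r_vertical = mean(reps$r_vertical)
  )
  attr(out, "repeats") <- reps
  out
}

#' Decoding accuracy as near-stimulus receptive fields are excluded
#'
#' For each volume and each distance threshold, grid ML decoding uses only
#' the voxels whose RF centres lie further than the threshold from the true
#' stimulus position at that volume; horizontal accuracy is reported per
#' threshold.  Volumes with no surviving voxel are skipped for that
#' threshold and counted.
#'
#' @param fits A selected `prf_fits` tibble.
#' @param series A long `voxel_series` tibble (test data).
#' @param volumes The matching volume series (true positions).
#' @param thresholds Ascending distance thresholds in degrees, starting at 0
#'   (default 0 to 4 in 0.5 steps).
#' @param grid,spec See [build_likelihood_table()].
#' @return A tibble with one row per threshold: `threshold`, `r_horizontal`,
#'   `n_volumes` (volumes decoded), `n_skipped`.
#' @export
distance_exclusion_curve <- function(fits, series, volumes,
                                     thresholds = seq(0, 4, by = 0.5),
                                     grid = decoding_grid(),
                                     spec = stimulus_spec()) {
  stopifnot(!is.unsorted(thresholds), thresholds[1] == 0, nrow(fits) >= 1)
  tab <- build_likelihood_table(fits, grid, spec)
  sm <- series_matrix(series)
  keep <- match(fits$voxel, sm$voxel)
  stopifnot(!anyNA(keep))
  A <- sm$amplitudes[, keep, drop = FALSE]
  stopifnot(nrow(A) == nrow(volumes))
  P <- tab$pred                       # voxels x grid
  w <- tab$weights
  G <- ncol(P)
  nt <- nrow(volumes)
  nth <- length(thresholds)

  pred_x <- matrix(NA_real_, nt, nth)
  pred_y <- matrix(NA_real_, nt, nth)
  gx <- grid$positions$gx
  gy <- grid$positions$gy
  for (t in seq_len(nt)) {
    dist_v <- sqrt((fits$mu_x - volumes$sx[t])^2 +
                   (fits$mu_y - volumes$sy[t])^2)
    Q <- w * (A[t, ] - P)^2           # voxels x grid, recycled by column
    ord <- order(dist_v, decreasing = TRUE)
    acc <- numeric(G)
    pos <- 1L
    # walk thresholds from the largest down, accumulating voxels whose RF
    # centre distance exceeds each threshold (suffix sums over sorted voxels)
    for (k in rev(seq_len(nth))) {
      while (pos <= length(ord) && dist_v[ord[pos]] > thresholds[k]) {
        acc <- acc + Q[ord[pos], ]
        pos <- pos + 1L
      }
      if (pos > 1L) {
        g <- which.min(acc)
        pred_x[t, k] <- gx[g]
        pred_y[t, k] <- gy[g]
      }
    }
  }

  purrr::map_dfr(seq_len(nth), function(k) {
    ok <- !is.na(pred_x[, k])
    rh <- if (sum(ok) >= 3 && stats::sd(pred_x[ok, k]) > 1e-12) {
      stats::cor(volumes$sx[ok], pred_x[ok, k])
    } else NA_real_
    tibble::tibble(threshold = thresholds[k], r_horizontal = rh,
                   n_volumes = sum(ok), n_skipped = sum(!ok))
  })
}

#' Fit an exponential decay to an accuracy-vs-threshold curve
#'
#' Least-squares fit of `y(d) = amplitude * exp(-d / tau) + baseline` with
#' `tau > 0`, multistarted over a grid of initial decay constants; the decay
#' constant tau measures how steeply accuracy collapses as near-stimulus
#' receptive fields are excluded.  tau is bounded above at five times the
#' sampled threshold range — beyond that the exponential is locally linear
#' over the data and tau is not identifiable; fits pegged at the bound (or
#' flat or non-decaying curves) are flagged.
#'
#' @param curve A tibble with columns `threshold` and an accuracy column
#'   (`r_horizontal` or `accuracy`); >= 4 finite points required.
#' @param tau_starts Initial tau values for the multistart.
#' @return An object of class `"decay_fit"`: `tau`, `amplitude`, `baseline`,
#'   `residual_sse`, `identifiable` (FALSE when the curve is flat or
#'   non-decaying, in which case tau is unreliable).
#' @export
fit_exponential_decay <- function(curve,
                                  tau_starts = c(0.25, 0.5, 1, 2, 4)) {
  ycol <- intersect(c("accuracy", "r_horizontal"), names(curve))[1]
  if (is.na(ycol)) stop("no accuracy column found", call. = FALSE)
  d <- curve$threshold
  y <- curve[[ycol]]
  ok <- is.finite(d) & is.finite(y)
  d <- d[ok]; y <- y[ok]
  if (length(d) < 4) stop("need at least 4 finite points", call. = FALSE)

  # tau is restricted to 5x the sampled threshold range: beyond that the
  # exponential is locally linear and tau trades off freely against the
  # amplitude, so larger values carry no information.  A fit pegged at the
  # bound is reported but flagged unidentifiable.
  tau_max <- 5 * (max(d) - min(d))
  best <- NULL
  for (tau0 in pmin(tau_starts, tau_max / 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * exp(-d / tau) + b,
        start = list(a = max(y) - min(y), b = min(y), tau = tau0),
        lower = c(a = -Inf, b = -Inf, tau = 1e-6),
        upper = c(a = Inf, b = Inf, tau = tau_max),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) {
      cf <- stats::coef(fit)
      best <- list(a = cf[["a"]], b = cf[["b"]], tau = cf[["tau"]], sse = sse)
    }
  }
  if (is.null(best)) {
    best <- list(a = 0, b = mean(y), tau = NA_real_,
                 sse = sum((y - mean(y))^2))
  }
  span <- max(y) - min(y)
  identifiable <- !is.na(best$tau) && abs(best$a) > 0.05 * max(span, 1e-12) &&
    span > 1e-8 && best$a > 0 && best$tau < 0.999 * tau_max
  structure(
    list(tau = best$tau, amplitude = best$a, baseline = best$b,
         residual_sse = best$sse, identifiable = identifiable,
         data = tibble::tibble(threshold = d, accuracy = y)),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> tau = %.3f deg, amplitude = %.3f, baseline = %.3f%s\n",
    x$tau, x$amplitude, x$baseline,
    if (!x$identifiable) " [tau unidentifiable]" else ""
  ))
  invisible(x)
}

#' One-way fixed-effects ANOVA across groups
#'
#' Standard one-way F statistic (equal-variance), as used to compare
#' Fisher-z accuracies or mean RF sizes across areas.
#'
#' @param groups A list of numeric vectors (>= 2 groups, each >= 2 values),
#'   or a data frame with columns `value` and `group`.
#' @return A one-row tibble: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`.
#' @export
one_way_f <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  n <- length(value)
  k <- length(groups)
  if (stats::var(value) < 1e-24) {   # all equal: F = 0 by convention
    return(tibble::tibble(f_statistic = 0, df_between = as.integer(k - 1),
                          df_within = as.integer(n - k), p_value = 1))
  }
  ht <- stats::oneway.test(value ~ grp, var.equal = TRUE)
  tibble::tibble(
    f_statistic = unname(ht$statistic),
    df_between = as.integer(ht$parameter[["num df"]]),
    df_within = as.integer(ht$parameter[["denom df"]]),
    p_value = unname(ht$p.value)
  )
}

#' Paired t test
#'
#' Paired t statistic on the differences `a - b` with `n - 1` degrees of
#' freedom (applied to Fisher-z accuracies in the pipeline).  Zero-variance
#' differences are flagged: t is 0 when the differences are all zero and
#' signed infinite otherwise.
#'
#' @param a,b Paired numeric vectors of equal length >= 2.
#' @return A one-row tibble: `t_statistic`, `df`, `p_value`,
#'   `zero_variance`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  dd <- a - b
  n <- length(dd)
  if (stats::sd(dd) < 1e-12) {
    t <- if (abs(mean(dd)) < 1e-12) 0 else sign(mean(dd)) * Inf
    return(tibble::tibble(
      t_statistic = t, df = n - 1L,
      p_value = if (t == 0) 1 else 0, zero_variance = TRUE
    ))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(
    t_statistic = unname(ht$statistic), df = as.integer(ht$parameter),
    p_value = unname(ht$p.value), zero_variance = FALSE
  )
}

#' t-based confidence interval across subjects
#'
#' `mean +/- t_{n-1, (1+level)/2} * sd / sqrt(n)`, the standard interval for
#' a small number of subjects.
#'
#' @param values Per-subject scalars (n >= 2).
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `mean`, `ci_low`, `ci_high`, `n`.
#' @export
ci_across_subjects <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  m <- mean(values)
  half <- stats::qt((1 + level) / 2, n - 1) * stats::sd(values) / sqrt(n)
  tibble::tibble(mean = m, ci_low = m - half, ci_high = m + half, n = n)
}
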