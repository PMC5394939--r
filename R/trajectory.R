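#' Configuration of the random stimulus trajectory
#'
#' The stimulus is a disk whose centre performs a momentum random walk inside
#' a square field: at every frame the centre moves a fixed distance `speed_c`
#' along a unit direction vector, and the direction is perturbed by isotropic
#' Gaussian noise of standard deviation `sigma_stim` and renormalised.  When a
#' provisional step would leave the allowed field, the offending component(s)
#' of the direction vector are sign-flipped before the step is taken, so the
#' centre reflects off the field edges.
#'
#' @param speed_c Step length per frame, degrees of visual angle.
#' @param sigma_stim Standard deviation of the per-frame direction noise
#'   (dimensionless; the perturbed direction is renormalised to unit length).
#' @param frame_rate Stimulus frame rate in Hz.
#' @param center_field_half_width Half-width, in degrees, of the square field
#'   the disk centre may occupy (default 3, i.e. a 6 x 6 degree field).
#' @param stimulus_radius Radius of the stimulus disk, degrees (default 0.8,
#'   i.e. a 1.6 degree diameter; the stimulus itself can span 7.6 x 7.6
#'   degrees).
#' @param seed Integer seed for the trajectory noise; `NULL` leaves the RNG
#'   state alone.
#' @param s0 Initial centre position (degrees), length-2 numeric.
#' @param p0 Initial unit direction, length-2 numeric, or `NULL` to draw a
#'   uniformly random angle.
#'
#' @return A list of class `"trajectory_config"`.
#' @export
trajectory_config <- function(speed_c = 0.008,
                              sigma_stim = 0.1,
                              frame_rate = 60,
                              center_field_half_width = 3,
                              stimulus_radius = 0.8,
                              seed = NULL,
                              s0 = c(0, 0),
                              p0 = NULL) {
  stopifnot(
    is.numeric(speed_c), length(speed_c) == 1, speed_c > 0,
    is.numeric(sigma_stim), length(sigma_stim) == 1, sigma_stim >= 0,
    is.numeric(frame_rate), length(frame_rate) == 1, frame_rate > 0,
    center_field_half_width > 0, stimulus_radius > 0,
    is.numeric(s0), length(s0) == 2,
    max(abs(s0)) <= center_field_half_width
  )
  if (!is.null(p0)) {
    stopifnot(is.numeric(p0), length(p0) == 2)
    nrm <- sqrt(sum(p0^2))
    if (nrm == 0) stop("`p0` must be a nonzero vector", call. = FALSE)
    p0 <- p0 / nrm
  }
  structure(
    list(
      speed_c = speed_c, sigma_stim = sigma_stim, frame_rate = frame_rate,
      center_field_half_width = center_field_half_width,
      stimulus_radius = stimulus_radius, seed = seed, s0 = s0, p0 = p0
    ),
    class = "trajectory_config"
  )
}

#' Simulate the momentum random walk of the stimulus centre
#'
#' Per frame the centre position `s` is updated by `s + c * p` with `p` a unit
#' direction vector; `p` then receives additive 2-D Gaussian noise with
#' covariance `sigma_stim^2 * I` and is renormalised.  Before every step the
#' provisional position is tested per axis against the field bound; any
#' component of `p` whose axis would leave the field is multiplied by -1
#' before the step is committed (corner hits flip both components).
#'
#' @param config A [trajectory_config()].
#' @param n_frames Number of frames to simulate (positions returned, the
#'   first being the initial position).
#'
#' @return A tibble of class `"prf_trajectory"` with one row per frame and
#'   columns `frame`, `sx`, `sy` (centre position, degrees) and `px`, `py`
#'   (unit direction used for the step out of that frame).
#' @export
simulate_trajectory <- function(config = trajectory_config(), n_frames) {
  stopifnot(inherits(config, "trajectory_config"))
  if (!is.numeric(n_frames) || length(n_frames) != 1 || n_frames < 1) {
    stop("`n_frames` must be a positive count", call. = FALSE)
  }
  n_frames <- as.integer(n_frames)

  sim <- function() {
    hw <- config$center_field_half_width
    cc <- config$speed_c
    s <- matrix(NA_real_, n_frames, 2)
    p <- matrix(NA_real_, n_frames, 2)
    s[1, ] <- config$s0
    if (is.null(config$p0)) {
      th <- stats::runif(1, 0, 2 * pi)
      pcur <- c(cos(th), sin(th))
    } else {
      pcur <- config$p0
    }
    eps <- matrix(stats::rnorm(2L * n_frames, sd = config$sigma_stim),
                  n_frames, 2)
    for (t in seq_len(n_frames)) {
      if (t < n_frames) {
        scur <- s[t, ]
        prov <- scur + cc * pcur
        if (abs(prov[1]) > hw) pcur[1] <- -pcur[1]
        if (abs(prov[2]) > hw) pcur[2] <- -pcur[2]
        p[t, ] <- pcur
        s[t + 1, ] <- scur + cc * pcur
        pn <- pcur + eps[t, ]
        pcur <- pn / sqrt(sum(pn^2))
      } else {
        p[t, ] <- pcur
      }
    }
    list(s = s, p = p)
  }

  out <- if (is.null(config$seed)) sim() else withr::with_seed(config$seed, sim())
  traj <- tibble::tibble(
    frame = seq_len(n_frames),
    sx = out$s[, 1], sy = out$s[, 2],
    px = out$p[, 1], py = out$p[, 2]
  )
  class(traj) <- c("prf_trajectory", class(traj))
  attr(traj, "config") <- config
  traj
}

#' Run schedule of the position-tracking experiment
#'
#' One run consists of an initial rest, four 240-s stimulus blocks separated
#' by 12-s rests, and a final 12-s rest (1040 s in total with the defaults).
#' fMRI volumes are acquired every `tr_s` seconds; volumes paired with
#' stimulus positions are shifted by `hemodynamic_shift_s` to compensate for
#' hemodynamic delay, and the first `discard_initial_s` of scanning are
#' discarded for scanner stabilisation (both fall in rest periods and thus
#' contribute no stimulus volumes).
#'
#' @param initial_rest_s,block_duration_s,n_blocks,inter_block_rest_s,final_rest_s
#'   Schedule durations in seconds / block count.
#' @param tr_s Volume repetition time, seconds.
#' @param hemodynamic_shift_s Hemodynamic delay compensation, seconds.
#' @param discard_initial_s Initial scans discarded, seconds.
#'
#' @return A list of class `"run_schedule"`.
#' @export
run_schedule <- function(initial_rest_s = 32, block_duration_s = 240,
                         n_blocks = 4, inter_block_rest_s = 12,
                         final_rest_s = 12, tr_s = 2,
                         hemodynamic_shift_s = 4, discard_initial_s = 8) {
  durs <- c(initial_rest_s, block_duration_s, inter_block_rest_s,
            final_rest_s, tr_s, hemodynamic_shift_s, discard_initial_s)
  stopifnot(all(durs >= 0), n_blocks >= 1, tr_s > 0)
  if (block_duration_s %% tr_s != 0) {
    stop("`block_duration_s` must be divisible by `tr_s`", call. = FALSE)
  }
  structure(
    list(
      initial_rest_s = initial_rest_s, block_duration_s = block_duration_s,
      n_blocks = n_blocks, inter_block_rest_s = inter_block_rest_s,
      final_rest_s = final_rest_s, tr_s = tr_s,
      hemodynamic_shift_s = hemodynamic_shift_s,
      discard_initial_s = discard_initial_s
    ),
    class = "run_schedule"
  )
}

#' Total duration of one run
#'
#' @param schedule A [run_schedule()].
#' @return Duration in seconds: initial rest + blocks + inter-block rests +
#'   final rest.
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "run_schedule"))
  schedule$initial_rest_s +
    schedule$n_blocks * schedule$block_duration_s +
    max(schedule$n_blocks - 1, 0) * schedule$inter_block_rest_s +
    schedule$final_rest_s
}

#' Number of stimulus frames needed per run
#'
#' Frames are simulated for stimulus-presentation blocks only (the disk is
#' absent during rest periods).
#'
#' @param schedule A [run_schedule()].
#' @param frame_rate Frames per second.
#' @return Integer frame count.
#' @export
frames_per_run <- function(schedule, frame_rate = 60) {
  stopifnot(inherits(schedule, "run_schedule"))
  as.integer(round(schedule$n_blocks * schedule$block_duration_s * frame_rate))
}

#' Map frame-level stimulus positions to fMRI volumes
#'
#' Each stimulus-presentation volume is assigned the position of the frame at
#' the midpoint of its TR window (frame index `tr_s * frame_rate * k +
#' tr_s * frame_rate / 2` within the block, 0-based), an unbiased single
#' representative of the window.  Rest-period volumes carry no stimulus and
#' are excluded.  The hemodynamic shift pairs each stimulus volume with the
#' activity measured `hemodynamic_shift_s` later; since downstream analyses
#' consume position/amplitude pairs, the returned series is already in paired
#' order.
#'
#' @param trajectory A [simulate_trajectory()] tibble covering at least
#'   `n_runs * frames_per_run(schedule)` frames (blocks are concatenated,
#'   run after run).
#' @param schedule A [run_schedule()].
#' @param n_runs Number of runs.
#' @param frame_rate Frames per second of the trajectory.
#'
#' @return A tibble of class `"volume_series"` with columns `volume` (global
#'   index), `run`, `sx`, `sy`.
#' @export
frames_to_volumes <- function(trajectory, schedule, n_runs, frame_rate = 60) {
  stopifnot(inherits(schedule, "run_schedule"), n_runs >= 1)
  fpr <- frames_per_run(schedule, frame_rate)
  need <- n_runs * fpr
  if (nrow(trajectory) < need) {
    stop(sprintf("trajectory has %d frames but %d are required for %d run(s)",
                 nrow(trajectory), need, n_runs), call. = FALSE)
  }
  fpv <- as.integer(round(schedule$tr_s * frame_rate))     # frames per volume
  vpb <- as.integer(schedule$block_duration_s / schedule$tr_s) # volumes per block
  fpb <- vpb * fpv                                          # frames per block

  idx <- integer(0)
  run <- integer(0)
  for (r in seq_len(n_runs)) {
    for (b in seq_len(schedule$n_blocks)) {
      off <- (r - 1L) * fpr + (b - 1L) * fpb
      k0 <- seq_len(vpb) - 1L
      idx <- c(idx, off + k0 * fpv + fpv %/% 2L + 1L)  # 1-based midpoint frame
      run <- c(run, rep.int(r, vpb))
    }
  }
  out <- tibble::tibble(
    volume = seq_along(idx),
    run = run,
    sx = trajectory$sx[idx],
    sy = trajectory$sy[idx]
  )
  class(out) <- c("volume_series", class(out))
  attr(out, "schedule") <- schedule
  out
}
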