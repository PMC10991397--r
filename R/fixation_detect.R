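# Velocity-based fixation detection: binocular gaze combination,
# Savitzky-Golay denoising, angular velocity, adaptive (data-driven)
# saccade threshold, and run segmentation with duration filtering.

#' Default gaze/fixation-detection parameters
#'
#' Savitzky-Golay window 20 ms / order 2, adaptive threshold initialized at
#' 100 deg/s with a 6 SD update and 1 deg/s convergence tolerance, fixation
#' durations restricted to \[100, 2500\] ms, and a flat-screen small-angle
#' geometry (0.51 m x 0.287 m screen at 0.65 m viewing distance, the middle
#' of the admissible 50-80 cm range).
#'
#' @return named list (the `gaze:` config block).
#' @export
gaze_params <- function() {
  list(sg_window_ms = 20, sg_order = 2,
       init_threshold = 100, k_sd = 6, tol = 1,
       min_fix_ms = 100, max_fix_ms = 2500,
       viewing_distance_m = 0.65,
       screen_w_m = 0.51, screen_h_m = 0.287,
       merge_ms = 0)
}

#' Combine binocular gaze into one series
#'
#' Same offset-aware fill-then-mean contract as [combine_eyes()], applied
#' independently per coordinate: the constant binocular disparity is
#' estimated over mutually valid samples, one-eye-missing samples are filled
#' from the other eye corrected by the disparity, and the output is the
#' per-sample mean.
#'
#' @param trial per-trial sample `data.frame` with `gaze_left_x` etc.
#' @return `data.frame` with `t`, `x`, `y`.
#' @export
combine_gaze <- function(trial) {
  data.frame(t = trial$t,
             x = combine_eyes(trial$gaze_left_x, trial$gaze_right_x),
             y = combine_eyes(trial$gaze_left_y, trial$gaze_right_y))
}

#' Savitzky-Golay denoising of a gaze series
#'
#' Polynomial least-squares smoothing per coordinate. Missing runs break the
#' filter: each maximal contiguous valid run is smoothed independently, and
#' runs shorter than the filter window pass through unchanged. The window
#' length in samples is derived from `window_ms` and the sample interval and
#' forced odd.
#'
#' @param gaze `data.frame` with `t`, `x`, `y`.
#' @param window_ms filter window (default 20 ms; 7 samples at 300 Hz).
#' @param poly_order polynomial order (default 2).
#' @return smoothed gaze `data.frame`.
#' @export
savgol_smooth <- function(gaze, window_ms = 20, poly_order = 2) {
  dt <- .nominal_dt(gaze$t)
  n <- round(window_ms / dt)
  if (n %% 2 == 0) n <- n + 1
  if (n <= poly_order)
    stop("Savitzky-Golay window (", n, " samples) must exceed poly_order")
  smooth_one <- function(v) {
    valid <- !is.na(v)
    r <- rle(valid)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      idx <- starts[j]:ends[j]
      if (length(idx) >= n)
        v[idx] <- signal::sgolayfilt(v[idx], p = poly_order, n = n)
    }
    v
  }
  gaze$x <- smooth_one(gaze$x)
  gaze$y <- smooth_one(gaze$y)
  gaze
}

#' Point-to-point angular gaze velocity
#'
#' Central-difference velocity in visual degrees per second under a
#' flat-screen small-angle model: normalized displacements are scaled by the
#' physical screen size and divided by the viewing distance. Velocity is
#' missing wherever either neighbour is missing.
#'
#' @param gaze `data.frame` with `t` (ms), `x`, `y` (normalized).
#' @param geometry list with `screen_w_m`, `screen_h_m`,
#'   `viewing_distance_m`.
#' @return numeric velocity series (deg/s), aligned with `gaze$t`.
#' @export
compute_velocity <- function(gaze, geometry = gaze_params()) {
  g <- geometry
  if (g$screen_w_m <= 0 || g$screen_h_m <= 0 || g$viewing_distance_m <= 0)
    stop("screen geometry must be positive")
  n <- nrow(gaze)
  v <- rep(NA_real_, n)
  if (n < 3) return(v)
  i <- 2:(n - 1)
  dx <- (gaze$x[i + 1] - gaze$x[i - 1]) * g$screen_w_m
  dy <- (gaze$y[i + 1] - gaze$y[i - 1]) * g$screen_h_m
  dt_s <- (gaze$t[i + 1] - gaze$t[i - 1]) / 1000
  deg <- sqrt(dx^2 + dy^2) / g$viewing_distance_m * 180 / pi
  v[i] <- deg / dt_s
  v
}

#' Adaptive data-driven velocity threshold
#'
#' Iterates `T <- mean + k_sd * SD` over the velocity samples at or below the
#' current threshold, starting from `init_deg_s`, until the threshold moves
#' by less than `tol` deg/s. With well-separated fixation and saccade
#' velocity modes the iteration settles between them.
#'
#' @param v velocity series (deg/s); NAs ignored.
#' @param init_deg_s initial threshold (default 100 deg/s).
#' @param k_sd SD multiplier (default 6).
#' @param tol convergence tolerance (default 1 deg/s).
#' @param max_iter iteration cap.
#' @param min_n minimum number of valid velocity samples required.
#' @return converged threshold (deg/s).
#' @export
adaptive_velocity_threshold <- function(v, init_deg_s = 100, k_sd = 6,
                                        tol = 1, max_iter = 100,
                                        min_n = 100) {
  v <- v[!is.na(v)]
  if (length(v) < min_n)
    stop("need at least ", min_n, " valid velocity samples, got ", length(v))
  thr <- init_deg_s
  for (it in seq_len(max_iter)) {
    sub <- v[v <= thr]
    if (length(sub) == 0) return(thr)  # nothing below: threshold is final
    s <- stats::sd(sub)
    if (length(sub) == 1 || !is.finite(s)) s <- 0
    new_thr <- mean(sub) + k_sd * s
    if (abs(new_thr - thr) < tol) return(new_thr)
    thr <- new_thr
  }
  stop("adaptive velocity threshold did not converge after ", max_iter,
       " iterations (last T = ", signif(thr, 4), " deg/s)")
}

#' Segment fixations from a velocity profile
#'
#' Maximal runs of valid samples with velocity strictly below the threshold
#' become candidate fixations. A candidate's duration is
#' `t[last] - t[first] + nominal dt`; candidates outside
#' `[min_dur, max_dur]` ms are dropped. The fixation location is the mean
#' gaze position over the run.
#'
#' @param gaze combined (smoothed) gaze `data.frame` (`t`, `x`, `y`).
#' @param velocity velocity series aligned with `gaze`.
#' @param threshold saccade velocity threshold (deg/s).
#' @param min_dur,max_dur retained duration range (default 100-2500 ms,
#'   inclusive; shorter and longer events are excluded).
#' @return `data.frame` of fixation events: `onset`, `offset`, `duration`
#'   (ms, trial-relative), `x`, `y`; zero rows when no fixation survives
#'   (such trials are removed from fixation analyses downstream).
#' @export
segment_fixations <- function(gaze, velocity, threshold,
                              min_dur = 100, max_dur = 2500) {
  dt <- .nominal_dt(gaze$t)
  fix_sample <- !is.na(velocity) & velocity < threshold &
    !is.na(gaze$x) & !is.na(gaze$y)
  r <- rle(fix_sample)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(onset = numeric(0), offset = numeric(0),
                    duration = numeric(0), x = numeric(0), y = numeric(0))
  for (j in keep) {
    i0 <- starts[j]; i1 <- ends[j]
    dur <- gaze$t[i1] - gaze$t[i0] + dt
    if (dur < min_dur || dur > max_dur) next
    out <- rbind(out, data.frame(
      onset = gaze$t[i0], offset = gaze$t[i0] + dur, duration = dur,
      x = mean(gaze$x[i0:i1]), y = mean(gaze$y[i0:i1])))
  }
  rownames(out) <- NULL
  out
}

#' Detect fixations in one trial
#'
#' Full detection chain: binocular combination, Savitzky-Golay denoising,
#' angular velocity, per-trial adaptive threshold, and run segmentation with
#' duration filtering. If an AOI map is supplied, each fixation's mean
#' location is labelled (`eyes`/`mouth`/`other`/`offscreen`).
#'
#' @param trial per-trial sample `data.frame` from [segment_trials()].
#' @param params parameter list, see [gaze_params()].
#' @param aoi_map optional `aoi_map` for labelling.
#' @return fixation event `data.frame` (possibly zero rows), with the
#'   converged threshold as attribute `threshold`.
#' @export
detect_fixations <- function(trial, params = gaze_params(), aoi_map = NULL) {
  p <- utils::modifyList(gaze_params(), params)
  gaze <- combine_gaze(trial)
  gaze <- savgol_smooth(gaze, p$sg_window_ms, p$sg_order)
  vel <- compute_velocity(gaze, p)
  thr <- adaptive_velocity_threshold(vel, p$init_threshold, p$k_sd, p$tol)
  ev <- segment_fixations(gaze, vel, thr, p$min_fix_ms, p$max_fix_ms)
  meta <- attr(trial, "meta")
  if (!is.null(aoi_map) && !is.null(meta))
    ev$aoi <- assign_aoi(ev$x, ev$y, aoi_map, meta$stimulus)
  attr(ev, "threshold") <- thr
  attr(ev, "meta") <- meta
  ev
}
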