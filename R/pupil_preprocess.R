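# Pupil preprocessing chain: raw binocular samples -> baseline-corrected trace.
#
# All filters operate on a numeric series x aligned to a time vector t (ms).
# Missingness is NA; every filter may only add NA, never restore values.
# MAD throughout is the raw (unscaled) median absolute deviation, floored at
# the instrument's diameter-quantization scale (default 0.002 mm) so that
# noiseless or quantization-limited series lose nothing: without the floor
# the robust spread of a smooth series collapses to numerical noise and the
# filters excise genuine signal structure.

.mad_floor_mm_default <- 0.002

.mad_raw <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  stats::median(abs(x - stats::median(x)))
}

# indices of previous/next valid sample for every position (NA-aware)
.prev_valid <- function(valid) {
  idx <- ifelse(valid, seq_along(valid), 0L)
  idx <- cummax(idx)
  idx[idx == 0L] <- NA_integer_
  idx
}
.next_valid <- function(valid) {
  n <- length(valid)
  rev(n + 1L - .prev_valid(rev(valid)))
}

# mean of valid x over the inclusive time window [t_i - half, t_i + half];
# exact in ms via cumulative sums (grid need not be uniform)
.window_mean <- function(t, x, half) {
  tol <- 1e-6
  lo <- findInterval(t - half - tol, t) + 1L
  hi <- findInterval(t + half + tol, t)
  valid <- !is.na(x)
  cx <- c(0, cumsum(ifelse(valid, x, 0)))
  cn <- c(0, cumsum(as.numeric(valid)))
  s <- cx[hi + 1L] - cx[lo]
  n <- cn[hi + 1L] - cn[lo]
  out <- s / n
  out[n == 0] <- NA_real_
  out
}

# missing runs of a series: one row per interior/exterior NA run with the
# flanking valid indices (NA when the run touches the series boundary) and
# the gap duration = missing-time span (t[next] - t[prev] - nominal dt)
.missing_runs <- function(t, x) {
  valid <- !is.na(x)
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  miss <- which(!r$values)
  if (length(miss) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      prev = integer(0), nxt = integer(0),
                      duration = numeric(0)))
  dt <- .nominal_dt(t)
  start <- starts[miss]; end <- ends[miss]
  prev <- ifelse(start > 1L, start - 1L, NA_integer_)
  nxt <- ifelse(end < length(x), end + 1L, NA_integer_)
  dur <- ifelse(is.na(prev) | is.na(nxt), NA_real_, t[nxt] - t[prev] - dt)
  data.frame(start = start, end = end, prev = prev, nxt = nxt, duration = dur)
}

#' Remove physiologically invalid pupil sizes
#'
#' Values strictly below `min_mm` or strictly above `max_mm` become missing;
#' the bounds themselves are retained.
#'
#' @param x pupil diameter series (mm).
#' @param min_mm,max_mm validity bounds (defaults 2 and 8 mm).
#' @return filtered series.
#' @export
filter_invalid_sizes <- function(x, min_mm = 2, max_mm = 8) {
  if (min_mm >= max_mm) stop("min_mm must be below max_mm")
  x[!is.na(x) & (x < min_mm | x > max_mm)] <- NA_real_
  x
}

#' Remove dilation-speed outliers
#'
#' Per-sample dilation speed is the maximum of the absolute slopes (mm/ms)
#' to the preceding and following valid neighbours, normalized by the actual
#' time deltas so the measure is robust to gaps. Samples whose speed exceeds
#' `median + k * MAD` of all speeds become missing. MAD is unscaled with an
#' epsilon floor, so constant series lose nothing.
#'
#' @param t time vector (ms).
#' @param x pupil series (mm).
#' @param k MAD multiplier (default 3).
#' @param mad_floor_mm MAD floor expressed as a diameter step per nominal
#'   sample interval (default 0.002 mm).
#' @return filtered series.
#' @export
dilation_speed_filter <- function(t, x, k = 3,
                                  mad_floor_mm = .mad_floor_mm_default) {
  valid <- !is.na(x)
  if (sum(valid) < 3) return(x)
  vi <- which(valid)
  xv <- x[vi]; tv <- t[vi]
  slope <- abs(diff(xv)) / diff(tv)
  back <- c(NA, slope)   # slope to preceding valid neighbour
  fwd <- c(slope, NA)    # slope to following valid neighbour
  speed <- pmax(back, fwd, na.rm = TRUE)
  med <- stats::median(speed, na.rm = TRUE)
  thr <- med + k * max(.mad_raw(speed), mad_floor_mm / .nominal_dt(t))
  drop <- vi[!is.na(speed) & speed > thr]
  x[drop] <- NA_real_
  x
}

#' Remove samples flanking blink-like gaps
#'
#' Missing runs whose duration lies in `(gap_min, gap_max]` ms are treated as
#' blinks; valid samples within `margin` ms (inclusive) of either end of such
#' a run become missing, because the closing/opening eyelid distorts the
#' pupil estimate. Gap duration is the missing-time span
#' (`t[next valid] - t[last valid] - nominal dt`), so an n-sample run at
#' 300 Hz has duration n * 10/3 ms. Runs touching the series boundary have
#' unknown duration and are left untouched.
#'
#' @param t time vector (ms).
#' @param x pupil series.
#' @param gap_min,gap_max blink duration range, default (75, 250] ms.
#' @param margin margin removed on each side (default 25 ms).
#' @return filtered series.
#' @export
blink_margin_removal <- function(t, x, gap_min = 75, gap_max = 250,
                                 margin = 25) {
  runs <- .missing_runs(t, x)
  runs <- runs[!is.na(runs$duration) &
                 runs$duration > gap_min & runs$duration <= gap_max, ,
               drop = FALSE]
  if (nrow(runs) == 0) return(x)
  tol <- 1e-6
  for (i in seq_len(nrow(runs))) {
    t_lo <- t[runs$prev[i]]; t_hi <- t[runs$nxt[i]]
    x[t >= t_lo - margin - tol & t <= t_lo + tol] <- NA_real_
    x[t >= t_hi - tol & t <= t_hi + margin + tol] <- NA_real_
  }
  x
}

#' Two-pass trend-line outlier removal
#'
#' Pass 1 estimates a smooth trend (centered moving average over valid
#' samples, `span_ms` window) and removes samples deviating more than
#' `k * MAD` of the residuals from it; pass 2 re-estimates the trend on the
#' survivors and removes again.
#'
#' @param t time vector (ms).
#' @param x pupil series.
#' @param k MAD multiplier (default 3).
#' @param span_ms trend smoother span (default 250 ms).
#' @param mad_floor_mm residual MAD floor (default 0.002 mm).
#' @return twice-filtered series.
#' @export
trendline_filter_two_pass <- function(t, x, k = 3, span_ms = 250,
                                      mad_floor_mm = .mad_floor_mm_default) {
  for (pass in 1:2) {
    if (sum(!is.na(x)) == 0) {
      attr(x, "fully_invalid") <- TRUE
      return(x)
    }
    trend <- .window_mean(t, x, span_ms / 2)
    resid <- x - trend
    med <- stats::median(resid, na.rm = TRUE)
    thr <- k * max(.mad_raw(resid), mad_floor_mm)
    x[!is.na(resid) & abs(resid - med) > thr] <- NA_real_
  }
  if (sum(!is.na(x)) == 0) attr(x, "fully_invalid") <- TRUE
  x
}

#' Combine the two eyes into one series
#'
#' The constant individual offset between eyes is estimated as
#' `mean(left - right)` over mutually valid samples; samples where one eye is
#' missing are filled from the other eye corrected by the offset, and the
#' output is the per-sample mean of the (filled) eyes. Samples missing in
#' both eyes stay missing.
#'
#' @param left,right equal-length aligned series.
#' @return combined series.
#' @export
combine_eyes <- function(left, right) {
  stopifnot(length(left) == length(right))
  both <- !is.na(left) & !is.na(right)
  if (!any(both)) {
    warning("no mutually valid samples; assuming zero inter-eye offset")
    offset <- 0
  } else {
    offset <- mean(left[both] - right[both])
  }
  lf <- ifelse(is.na(left) & !is.na(right), right + offset, left)
  rf <- ifelse(is.na(right) & !is.na(left), left - offset, right)
  (lf + rf) / 2
}

#' Interpolate short missing runs
#'
#' Interior missing runs with duration `<= max_gap` ms (missing-time span,
#' see [blink_margin_removal()]) are linearly interpolated between the
#' flanking valid values; longer runs and leading/trailing runs are left
#' untouched.
#'
#' @param t time vector (ms).
#' @param x series.
#' @param max_gap maximum interpolated gap (default 300 ms).
#' @return series with short gaps filled.
#' @export
interpolate_gaps <- function(t, x, max_gap = 300) {
  runs <- .missing_runs(t, x)
  runs <- runs[!is.na(runs$duration) & runs$duration <= max_gap + 1e-6, ,
               drop = FALSE]
  for (i in seq_len(nrow(runs))) {
    p <- runs$prev[i]; nx <- runs$nxt[i]
    idx <- runs$start[i]:runs$end[i]
    x[idx] <- x[p] + (x[nx] - x[p]) * (t[idx] - t[p]) / (t[nx] - t[p])
  }
  x
}

#' Centered moving-average smoothing
#'
#' Mean over all valid samples within `span/2` ms (inclusive) of each sample;
#' the window renormalizes over its valid members. Missing samples stay
#' missing.
#'
#' @param t time vector (ms).
#' @param x series.
#' @param span smoothing span (default 30 ms; 9 samples at 300 Hz).
#' @return smoothed series.
#' @export
smooth_moving_average <- function(t, x, span = 30) {
  out <- .window_mean(t, x, span / 2)
  out[is.na(x)] <- NA_real_
  out
}

#' Baseline-correct a trial trace
#'
#' Subtracts the mean pupil size over the first `baseline_ms` of the trial.
#' The analysis portion of the trace starts at `baseline_ms`.
#'
#' @param t trial-relative time (ms).
#' @param x combined, smoothed pupil series (mm).
#' @param baseline_ms baseline window (default 500 ms).
#' @return list with `response` (x minus baseline mean), `baseline` (mm), and
#'   `baseline_valid` (FALSE when no valid baseline samples exist, in which
#'   case `response` is all-NA and the trial must be excluded).
#' @export
baseline_correct <- function(t, x, baseline_ms = 500) {
  sel <- t < baseline_ms
  bl <- mean(x[sel], na.rm = TRUE)
  if (!is.finite(bl))
    return(list(response = rep(NA_real_, length(x)), baseline = NA_real_,
                baseline_valid = FALSE))
  list(response = x - bl, baseline = bl, baseline_valid = TRUE)
}

#' Default pupil preprocessing parameters
#'
#' All thresholds of the preprocessing chain with their standard defaults:
#' validity bounds 2-8 mm, dilation-speed and trend-line MAD multipliers 3,
#' blink gap range (75, 250] ms with 25 ms margins, 250 ms trend span,
#' 300 ms maximum interpolated gap, 30 ms smoothing span, 500 ms baseline,
#' and a 50% minimum valid fraction per trial.
#'
#' @return named list of parameters (the `pupil:` config block).
#' @export
pupil_params <- function() {
  list(min_mm = 2, max_mm = 8, speed_k = 3, mad_floor_mm = 0.002,
       blink_gap_min = 75, blink_gap_max = 250, blink_margin = 25,
       trend_k = 3, trend_span_ms = 250,
       interp_max = 300, smooth_span = 30,
       baseline_ms = 500, trial_min_valid = 0.5, window_ms = 4500)
}

#' Preprocess one trial's pupil data
#'
#' Applies the full chain: off-screen removal, size filter, dilation-speed
#' filter, blink margins and two-pass trend filter per eye; then binocular
#' combination, gap interpolation, moving-average smoothing and baseline
#' correction. The valid fraction is the share of non-missing samples over
#' all nominal samples in the trial window; trials with a valid fraction
#' strictly below `trial_min_valid` are flagged excluded.
#'
#' @param trial per-trial sample `data.frame` from [segment_trials()].
#' @param params parameter list, see [pupil_params()].
#' @return a `pupil_trace`: list with `t`, `response`, `baseline`,
#'   `valid_fraction`, `excluded`, `exclude_reason`, and the trial `meta`.
#' @export
preprocess_trial <- function(trial, params = pupil_params()) {
  p <- utils::modifyList(pupil_params(), params)
  t <- trial$t
  n_nominal <- round(p$window_ms / .nominal_dt(t))
  eyes <- list(left = trial$pupil_left, right = trial$pupil_right)
  ok_onscreen <- trial$onscreen %in% TRUE
  eyes <- lapply(eyes, function(x) {
    x[!ok_onscreen] <- NA_real_
    x <- filter_invalid_sizes(x, p$min_mm, p$max_mm)
    x <- dilation_speed_filter(t, x, p$speed_k, p$mad_floor_mm)
    x <- blink_margin_removal(t, x, p$blink_gap_min, p$blink_gap_max,
                              p$blink_margin)
    trendline_filter_two_pass(t, x, p$trend_k, p$trend_span_ms,
                              p$mad_floor_mm)
  })
  comb <- combine_eyes(eyes$left, eyes$right)
  comb <- interpolate_gaps(t, comb, p$interp_max)
  comb <- smooth_moving_average(t, comb, p$smooth_span)
  valid_fraction <- sum(!is.na(comb)) / n_nominal
  bc <- baseline_correct(t, comb, p$baseline_ms)
  excluded <- FALSE; reason <- NA_character_
  if (!bc$baseline_valid) {
    excluded <- TRUE; reason <- "no_valid_baseline"
  } else if (valid_fraction < p$trial_min_valid) {
    excluded <- TRUE; reason <- "valid_fraction_below_0.5"
  }
  structure(list(t = t, response = bc$response, baseline = bc$baseline,
                 valid_fraction = valid_fraction, excluded = excluded,
                 exclude_reason = reason, baseline_ms = p$baseline_ms,
                 meta = attr(trial, "meta")),
            class = "pupil_trace")
}
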