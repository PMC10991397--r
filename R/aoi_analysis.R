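# AOI assignment and the three gaze outcomes: fixation count, mean fixation
# duration, and 50 ms looking-time progression; plus the data-quality
# covariates (onscreen time, gaze deviation from screen center).

.aoi_levels <- c("eyes", "mouth", "other", "offscreen")

#' Assign gaze points to AOI labels
#'
#' Rectangle membership is inclusive on the left/top edge and exclusive on
#' the right/bottom edge, so a point on a shared boundary receives exactly
#' one label. Points outside the unit square or missing are `offscreen`;
#' on-screen points outside both rectangles are `other`. Body/background
#' regions, if present in the map, are representable but fold into `other`
#' (they are excluded from the outcomes).
#'
#' @param x,y normalized gaze coordinates (vectors).
#' @param aoi_map an `aoi_map`.
#' @param stimulus stimulus name (scalar) keying the map.
#' @return factor with levels `eyes`, `mouth`, `other`, `offscreen`.
#' @export
assign_aoi <- function(x, y, aoi_map, stimulus) {
  stim <- aoi_map[[as.character(stimulus)]]
  if (is.null(stim)) stop("stimulus '", stimulus, "' not in AOI map")
  lab <- rep("offscreen", length(x))
  on <- !is.na(x) & !is.na(y) & x >= 0 & x <= 1 & y >= 0 & y <= 1
  lab[on] <- "other"
  in_rect <- function(r)
    on & x >= r[1] & x < r[1] + r[3] & y >= r[2] & y < r[2] + r[4]
  lab[in_rect(stim$mouth)] <- "mouth"
  lab[in_rect(stim$eyes)] <- "eyes"
  factor(lab, levels = .aoi_levels)
}

#' Per-trial fixation outcomes
#'
#' For every trial x AOI (eyes, mouth): the number of fixations whose mean
#' location lies in the AOI and the mean duration across those fixations
#' (NA when the count is 0; such cells are excluded from duration models).
#' Trials with zero fixations anywhere contribute no rows and are listed in
#' the `no_fixation_trials` attribute.
#'
#' @param events named list of fixation-event `data.frame`s (one per trial,
#'   as returned by [detect_fixations()] with an AOI map).
#' @return `data.frame`: `participant_id`, `trial_index`, `group`,
#'   `emotion`, `aoi`, `n_fixations`, `mean_duration`.
#' @export
fixation_outcomes <- function(events) {
  rows <- list()
  no_fix <- character(0)
  for (nm in names(events)) {
    ev <- events[[nm]]
    meta <- attr(ev, "meta")
    if (nrow(ev) == 0) {
      no_fix <- c(no_fix, nm)
      next
    }
    for (aoi in c("eyes", "mouth")) {
      sel <- ev$aoi == aoi
      rows[[paste(nm, aoi)]] <- data.frame(
        participant_id = meta$participant_id,
        trial_index = meta$trial_index,
        group = meta$group, emotion = meta$emotion,
        aoi = aoi, n_fixations = sum(sel),
        mean_duration = if (any(sel)) mean(ev$duration[sel]) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "no_fixation_trials") <- no_fix
  out
}

#' Bin looking time into 50 ms windows per AOI
#'
#' Every gaze sample (not only fixation samples) in the analysis window
#' `[window_start, window_end)` is assigned to its time bin and AOI; the
#' result is the per-bin sample count for each AOI label, including zeros.
#' At the defaults this yields 80 bins tiling 500-4500 ms.
#'
#' @param trial per-trial sample `data.frame` from [segment_trials()].
#' @param aoi_map an `aoi_map`.
#' @param bin_ms bin width (default 50 ms; must divide the window).
#' @param window_start,window_end analysis window (default 500-4500 ms,
#'   excluding the baseline period).
#' @return `data.frame`: `bin` (0-based), `time` (bin start, ms), one row
#'   per bin x AOI with `aoi` and `count`.
#' @export
bin_looking_time <- function(trial, aoi_map, bin_ms = 50,
                             window_start = 500, window_end = 4500) {
  span <- window_end - window_start
  if (span %% bin_ms != 0)
    stop("bin width ", bin_ms, " ms does not divide the ", span, " ms window")
  n_bins <- span %/% bin_ms
  gaze <- combine_gaze(trial)
  sel <- gaze$t >= window_start & gaze$t < window_end
  meta <- attr(trial, "meta")
  lab <- assign_aoi(gaze$x[sel], gaze$y[sel], aoi_map, meta$stimulus)
  bin <- pmin(floor((gaze$t[sel] - window_start) / bin_ms), n_bins - 1)
  tab <- table(factor(bin, levels = 0:(n_bins - 1)), lab)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("bin", "aoi", "count")
  out$bin <- as.integer(as.character(out$bin))
  out$time <- window_start + out$bin * bin_ms
  out <- out[order(out$aoi, out$bin), c("bin", "time", "aoi", "count")]
  rownames(out) <- NULL
  attr(out, "meta") <- meta
  out
}

#' Session-level data-quality covariates
#'
#' `onscreen_time` is the fraction of session samples with gaze located on
#' the screen; `gaze_deviation` is the mean Euclidean distance of on-screen
#' gaze (combined eyes) from the screen center (0.5, 0.5), in normalized
#' units.
#'
#' @param stream a `sample_stream` for one participant session.
#' @return one-row `data.frame` with `onscreen_time` and `gaze_deviation`.
#' @export
compute_covariates <- function(stream) {
  if (nrow(stream) == 0) stop("empty sample stream")
  x <- combine_eyes(stream$gaze_left_x, stream$gaze_right_x)
  y <- combine_eyes(stream$gaze_left_y, stream$gaze_right_y)
  on <- !is.na(x) & !is.na(y) & x >= 0 & x <= 1 & y >= 0 & y <= 1
  dev <- if (any(on)) mean(sqrt((x[on] - 0.5)^2 + (y[on] - 0.5)^2)) else NA_real_
  data.frame(onscreen_time = mean(on), gaze_deviation = dev)
}
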