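# Ground-truth-labelled synthetic data for a two-group emotion-viewing
# design: semi-Markov AOI scanpaths (time-varying eye/mouth preference),
# three-kernel pupil traces with AR(1) noise, and artifact injection
# (blinks, dilation-speed spikes, slow drift). Every dataset carries a
# truth object that fully determines the noiseless signal.

#' Default simulation parameters
#'
#' The generator emulates a two-group (ASD-like vs TD-like) design:
#' 30 participants per group, 12 trials of 4.5 s at 300 Hz (4 actors x 3
#' emotion expressions). Gaze follows a semi-Markov AOI process whose
#' eye/mouth dwell preferences are logistic in trial time; the ASD-like
#' group starts with a mouth preference and ends with an eye preference so
#' the group looking-time curves cross mid-trial. The pupil trace is a
#' participant baseline plus three gamma-shaped temporal kernels (early /
#' middle / late) scaled by trial amplitudes, with AR(1) noise; kernel
#' placement and amplitude spreads are chosen so the amplitude-weighted
#' dominance windows of the kernels fall at roughly 500-920, 920-2470 and
#' 2470-4500 ms. Group effects on pupil amplitudes default to zero (null);
#' a negative coupling links the early pupil amplitude to the trial's mouth
#' preference.
#'
#' @return nested named list of parameters.
#' @export
sim_params <- function() {
  list(
    rate_hz = 300, trial_ms = 4500, gap_ms = 2000,
    n_per_group = 30, n_trials = 12,
    actors = c("man", "woman", "boy", "girl"),
    emotions = c("fear", "happy", "neutral"),
    scanpath = list(
      fix_meanlog = log(300), fix_sdlog = 0.35, fix_min_ms = 60,
      saccade_ms = 30, jitter_sd = 0.003, disparity = 0.012,
      # logistic preferences: base + amp * plogis((t - mid) / scale)
      prefs = list(
        TD  = list(eyes  = c(base = 0.40, amp = 0.10, mid = 2200, scale = 500),
                   mouth = c(base = 0.32, amp = -0.04, mid = 2200, scale = 500)),
        ASD = list(eyes  = c(base = 0.20, amp = 0.36, mid = 2200, scale = 500),
                   mouth = c(base = 0.48, amp = -0.30, mid = 2200, scale = 500))),
      emotion_shift = list(fear = c(eyes = 0.03, mouth = 0),
                           happy = c(eyes = 0, mouth = 0.05),
                           neutral = c(eyes = 0, mouth = 0)),
      pref_shift_sd = 0.06),
    pupil = list(
      baseline_mean = 4.5, baseline_sd = 0.35,
      eye_offset_sd = 0.15, ar_phi = 0.98, ar_sd = 0.003,
      right_noise_sd = 0.01,
      kernels = list(c(t0 = 350, shape = 4, scale = 100),
                     c(t0 = 610, shape = 4, scale = 300),
                     c(t0 = 1980, shape = 4, scale = 480)),
      amp_mu = c(0.02, 0.06, 0.10),
      amp_sd = c(0.05, 0.08, 0.10),
      group_effect = c(0, 0, 0),       # ASD minus TD shift per amplitude
      coupling_a1_mouth = -0.04),
    artifacts = list(blink_per_min = 8, spike_per_min = 4,
                     drift_per_min = 1))
}

# gamma-shaped kernel normalized to unit peak (mode at t0 + (shape-1)*scale)
.pd_kernel <- function(t, par) {
  u <- (t - par[["t0"]]) / par[["scale"]]
  a <- par[["shape"]]
  out <- ifelse(u > 0, u^(a - 1) * exp(-u), 0)
  out / ((a - 1)^(a - 1) * exp(-(a - 1)))
}

#' Kernel basis matrix
#' @param t time vector (ms from trial onset).
#' @param params simulation parameters.
#' @return matrix `length(t)` x number of kernels, unit peak each.
#' @export
pd_kernel_basis <- function(t, params = sim_params()) {
  sapply(params$pupil$kernels, function(par) .pd_kernel(t, par))
}

#' True component windows implied by the kernel design
#'
#' At each time point the dominant kernel is the one with the largest
#' amplitude-spread-weighted value (`amp_sd[k] * kernel_k(t)`), mirroring
#' what a variance decomposition of the traces can see. The dominance
#' switch points are the true window boundaries.
#'
#' @param params simulation parameters.
#' @param window_start,window_end analysis window (ms).
#' @param step evaluation step (ms).
#' @return `data.frame` with `component`, `start_ms`, `end_ms`.
#' @export
true_component_windows <- function(params = sim_params(),
                                   window_start = 500, window_end = 4500,
                                   step = 1) {
  t <- seq(window_start, window_end, by = step)
  w <- params$pupil$amp_sd
  dom <- apply(pd_kernel_basis(t, params) %*% diag(w), 1, which.max)
  cuts <- t[which(diff(dom) != 0)]
  starts <- c(window_start, cuts)
  data.frame(component = paste0("T-RC", seq_along(starts)),
             start_ms = starts, end_ms = c(cuts, window_end))
}

# evaluate eye/mouth preference at trial times for one group x emotion,
# with an optional per-trial additive mouth shift
.preference <- function(t, group, emotion, sc, mouth_shift = 0) {
  pg <- sc$prefs[[group]]
  es <- sc$emotion_shift[[emotion]]
  lgt <- function(p) p[["base"]] + p[["amp"]] * stats::plogis((t - p[["mid"]]) / p[["scale"]])
  pe <- lgt(pg$eyes) + es[["eyes"]]
  pm <- lgt(pg$mouth) + es[["mouth"]]
  # configured weights must leave a nonnegative off-AOI remainder; the
  # per-trial mouth shift is a random perturbation and is clamped instead
  if (any(pe + pm > 1 + 1e-9) || any(pe < -1e-9) || any(pm < -1e-9))
    stop("AOI preference weights must lie in [0, 1] and sum to at most 1 ",
         "(remainder = off-AOI)")
  pm <- pm + mouth_shift
  pe <- pmin(pmax(pe, 0), 1)
  pm <- pmin(pmax(pm, 0), 1 - pe)
  cbind(eyes = pe, mouth = pm)
}

# alternating fixation/saccade segment plan tiling one trial
.scanpath_segments <- function(group, emotion, rects, params, mouth_shift) {
  sc <- params$scanpath
  trial_ms <- params$trial_ms
  seg <- list(); tcur <- 0
  while (tcur < trial_ms) {
    pref <- .preference(tcur, group, emotion, sc, mouth_shift)
    aoi <- sample(c("eyes", "mouth", "other"), 1,
                  prob = c(pref[1, "eyes"], pref[1, "mouth"],
                           1 - sum(pref[1, ])))
    target <- .draw_target(aoi, rects)
    dur <- max(sc$fix_min_ms,
               stats::rlnorm(1, sc$fix_meanlog, sc$fix_sdlog))
    seg[[length(seg) + 1]] <- list(kind = "fixation", onset = tcur,
                                   offset = min(tcur + dur, trial_ms),
                                   aoi = aoi, target = target)
    tcur <- tcur + dur
    if (tcur >= trial_ms) break
    seg[[length(seg) + 1]] <- list(kind = "saccade", onset = tcur,
                                   offset = min(tcur + sc$saccade_ms, trial_ms),
                                   aoi = "saccade", target = target)
    tcur <- tcur + sc$saccade_ms
  }
  seg
}

# draw a fixation target inside an AOI rectangle (small inset so jitter
# rarely leaves the region) or on the face area outside both AOIs
.draw_target <- function(aoi, rects) {
  inset <- 0.02
  if (aoi %in% c("eyes", "mouth")) {
    r <- rects[[aoi]]
    c(stats::runif(1, r[1] + inset, r[1] + r[3] - inset),
      stats::runif(1, r[2] + inset, r[2] + r[4] - inset))
  } else {
    repeat {
      p <- c(stats::runif(1, 0.25, 0.75), stats::runif(1, 0.05, 0.95))
      inside <- vapply(rects[c("eyes", "mouth")], function(r)
        p[1] >= r[1] && p[1] < r[1] + r[3] &&
          p[2] >= r[2] && p[2] < r[2] + r[4], logical(1))
      if (!any(inside)) return(p)
    }
  }
}

#' Simulate one trial's scanpath
#'
#' Alternating fixation/saccade segments tile the trial: at each fixation
#' onset the AOI is drawn from the time-varying preference (remainder =
#' off-AOI), a target point is drawn inside the region, the fixation
#' duration is lognormal (median ~300 ms), and a 30 ms saccade ramps
#' smoothly (cosine) to the next target. The emitted binocular gaze series
#' adds a constant horizontal disparity between eyes and small independent
#' Gaussian jitter per eye and sample.
#'
#' @param group `"ASD"` or `"TD"`.
#' @param emotion emotion expression of the trial.
#' @param rects named list with `eyes`/`mouth` rectangles.
#' @param params simulation parameters.
#' @param mouth_shift per-trial additive shift of the mouth preference.
#' @param jitter_sd gaze jitter SD (overrides params when not NULL).
#' @return list with `gaze` (`t`, `gaze_left_x/y`, `gaze_right_x/y`) and
#'   `fixations` (truth: `onset`, `offset`, `duration`, `aoi`, `x`, `y`).
#' @export
simulate_scanpath <- function(group, emotion, rects, params = sim_params(),
                              mouth_shift = 0, jitter_sd = NULL) {
  sc <- params$scanpath
  if (is.null(jitter_sd)) jitter_sd <- sc$jitter_sd
  trial_ms <- params$trial_ms
  dt <- 1000 / params$rate_hz
  seg <- .scanpath_segments(group, emotion, rects, params, mouth_shift)
  t <- seq(0, trial_ms - dt / 2, by = dt)
  pos <- matrix(NA_real_, length(t), 2)
  fix_rows <- list()
  for (j in seq_along(seg)) {
    s <- seg[[j]]
    idx <- which(t >= s$onset & t < s$offset)
    if (s$kind == "fixation") {
      pos[idx, 1] <- s$target[1]; pos[idx, 2] <- s$target[2]
      fix_rows[[length(fix_rows) + 1]] <- data.frame(
        onset = s$onset, offset = s$offset, duration = s$offset - s$onset,
        aoi = s$aoi, x = s$target[1], y = s$target[2])
    } else if (length(idx) > 0) {
      # smooth position ramp between the flanking fixation targets:
      # velocity peaks mid-saccade, near zero at the ends
      from <- seg[[j - 1]]$target
      to <- if (j < length(seg)) seg[[j + 1]]$target else from
      frac <- (t[idx] - s$onset) / (s$offset - s$onset)
      w <- (1 - cos(pi * frac)) / 2
      pos[idx, 1] <- from[1] + (to[1] - from[1]) * w
      pos[idx, 2] <- from[2] + (to[2] - from[2]) * w
    }
  }
  d <- sc$disparity / 2
  jit <- function(n) stats::rnorm(n, 0, jitter_sd)
  n <- length(t)
  gaze <- data.frame(
    t = t,
    gaze_left_x = pos[, 1] - d + jit(n), gaze_left_y = pos[, 2] + jit(n),
    gaze_right_x = pos[, 1] + d + jit(n), gaze_right_y = pos[, 2] + jit(n))
  fixations <- do.call(rbind, fix_rows)
  list(gaze = gaze, fixations = fixations)
}

#' Simulate one trial's binocular pupil trace
#'
#' Left eye = participant baseline + sum of kernel contributions
#' `a_k * kernel_k(t)` + AR(1) noise; right eye = left + constant individual
#' offset + independent white noise. With zero amplitudes and zero noise the
#' trace is flat at baseline.
#'
#' @param t time vector (ms from trial onset).
#' @param amplitudes numeric vector `(a1, a2, a3)` in mm.
#' @param baseline participant baseline diameter (mm, positive).
#' @param eye_offset constant right-minus-left offset (mm).
#' @param params simulation parameters.
#' @param noise logical; disable for noiseless traces.
#' @return `data.frame` with `pupil_left`, `pupil_right`.
#' @export
simulate_pupil_trace <- function(t, amplitudes, baseline, eye_offset = 0,
                                 params = sim_params(), noise = TRUE) {
  if (baseline <= 0) stop("baseline pupil diameter must be positive")
  pu <- params$pupil
  signal <- baseline + as.numeric(pd_kernel_basis(t, params) %*% amplitudes)
  n <- length(t)
  if (noise) {
    ar <- as.numeric(stats::arima.sim(list(ar = pu$ar_phi), n,
                                      sd = pu$ar_sd))
    left <- signal + ar
    right <- left + eye_offset + stats::rnorm(n, 0, pu$right_noise_sd)
  } else {
    left <- signal
    right <- left + eye_offset
  }
  data.frame(pupil_left = left, pupil_right = right)
}

#' Inject blink gaps, dilation-speed spikes, and slow drift
#'
#' Blinks are missing runs of 75-250 ms (pupil and gaze of both eyes);
#' spikes add an isolated step to one sample of both pupil series (a
#' dilation-speed outlier); drift excursions add a slow Gaussian bump
#' (~500 ms wide) to the pupil. All injected sample indices are recorded in
#' the returned truth.
#'
#' @param stream a session `data.frame` (sample-stream columns).
#' @param blink_per_min,spike_per_min,drift_per_min rates per minute (>= 0);
#'   all 0 leaves the stream unchanged.
#' @return list `stream` (modified) and `truth` (named list of injected
#'   index vectors).
#' @export
inject_artifacts <- function(stream, blink_per_min = 8, spike_per_min = 4,
                             drift_per_min = 1) {
  stopifnot(blink_per_min >= 0, spike_per_min >= 0, drift_per_min >= 0)
  n <- nrow(stream)
  dt <- .nominal_dt(stream$t)
  minutes <- n * dt / 60000
  draw_n <- function(rate) stats::rpois(1, rate * minutes)
  blink_idx <- integer(0); spike_idx <- integer(0); drift_idx <- integer(0)
  occupied <- rep(FALSE, n)
  for (b in seq_len(draw_n(blink_per_min))) {
    len <- sample(ceiling(75 / dt + 1e-9):floor(250 / dt + 1e-9), 1)
    start <- sample(seq_len(max(1, n - len)), 1)
    idx <- start:(start + len - 1)
    # keep blinks separated so each gap stays in the blink duration range
    pad <- max(1, start - 2):min(n, start + len + 1)
    if (any(occupied[pad])) next
    occupied[pad] <- TRUE
    for (cc in c("pupil_left", "pupil_right", "gaze_left_x", "gaze_left_y",
                 "gaze_right_x", "gaze_right_y"))
      stream[[cc]][idx] <- NA_real_
    blink_idx <- c(blink_idx, idx)
  }
  for (s in seq_len(draw_n(spike_per_min))) {
    i <- sample(n, 1)
    step <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.5)
    stream$pupil_left[i] <- stream$pupil_left[i] + step
    stream$pupil_right[i] <- stream$pupil_right[i] + step
    spike_idx <- c(spike_idx, i)
  }
  for (dd in seq_len(draw_n(drift_per_min))) {
    # drift excursion: Gaussian bump, 80 ms SD -- slower than a spike but
    # fast against the 250 ms trend span, so the trend filter can see it;
    # recorded truth indices are the materially distorted core (> 0.05 mm)
    center <- sample(n, 1)
    width <- 80 / dt
    amp <- sample(c(-1, 1), 1) * stats::runif(1, 0.3, 0.6)
    idx <- max(1, floor(center - 3 * width)):min(n, ceiling(center + 3 * width))
    bump <- amp * exp(-((idx - center)^2) / (2 * width^2))
    stream$pupil_left[idx] <- stream$pupil_left[idx] + bump
    stream$pupil_right[idx] <- stream$pupil_right[idx] + bump
    drift_idx <- c(drift_idx, idx[abs(bump) > 0.05])
  }
  if ("onscreen" %in% names(stream)) stream$onscreen <- .onscreen_flag(stream)
  list(stream = stream,
       truth = list(blink = sort(unique(blink_idx)),
                    spike = sort(unique(spike_idx)),
                    drift = sort(unique(drift_idx))))
}

#' Simulate a complete two-group dataset
#'
#' Generates, per participant: a session sample stream (trials separated by
#' fixation-cross gaps at screen center), the trial table, covariates, and
#' a truth object (group, per-trial emotion/amplitudes/fixation segments,
#' injected artifact indices, seed). Fully reproducible from
#' `(params, seed)`.
#'
#' @param params simulation parameters, see [sim_params()].
#' @param seed integer seed.
#' @param noise logical; FALSE yields noiseless, artifact-free data.
#' @param artifacts logical; FALSE skips artifact injection.
#' @return list with `streams` (named list of `sample_stream`s), `trials`
#'   (trial table), `participants` (covariates), `aoi_map`, `truth`,
#'   `params`, `seed`.
#' @export
simulate_dataset <- function(params = sim_params(), seed = 1,
                             noise = TRUE, artifacts = noise) {
  set.seed(seed)
  p <- params
  dt <- 1000 / p$rate_hz
  groups <- rep(c("ASD", "TD"), each = p$n_per_group)
  ids <- sprintf("P%03d", seq_along(groups))
  stimuli <- as.vector(outer(p$actors, p$emotions, paste, sep = "_"))
  aoi_map <- default_aoi_map(stimuli)
  rects <- aoi_map[[1]]
  participants <- data.frame(
    participant_id = ids, group = groups,
    age = round(stats::runif(length(ids), 20, 60)),
    sex = sample(c("male", "female"), length(ids), replace = TRUE),
    stringsAsFactors = FALSE)
  streams <- list(); trials_rows <- list(); truth_tr <- list()
  truth_art <- list()
  pu <- p$pupil
  for (i in seq_along(ids)) {
    pid <- ids[i]; grp <- groups[i]
    baseline <- max(3, stats::rnorm(1, pu$baseline_mean, pu$baseline_sd))
    eye_offset <- stats::rnorm(1, 0, pu$eye_offset_sd)
    order_stim <- sample(stimuli, p$n_trials)
    parts <- list(); onset <- 0
    ge <- if (grp == "ASD") pu$group_effect else c(0, 0, 0)
    for (k in seq_len(p$n_trials)) {
      stim <- order_stim[k]
      emo <- sub("^[a-z]+_", "", stim)
      actor <- sub("_[a-z]+$", "", stim)
      # inter-trial fixation cross at screen center
      tg <- seq(0, p$gap_ms - dt / 2, by = dt)
      gap_pup <- simulate_pupil_trace(tg + p$trial_ms, c(0, 0, 0), baseline,
                                      eye_offset, p, noise = noise)
      jsd <- if (noise) p$scanpath$jitter_sd else 0
      gap <- data.frame(t = onset + tg,
                        pupil_left = gap_pup$pupil_left,
                        pupil_right = gap_pup$pupil_right,
                        gaze_left_x = 0.5 - p$scanpath$disparity / 2 +
                          stats::rnorm(length(tg), 0, jsd),
                        gaze_left_y = 0.5 + stats::rnorm(length(tg), 0, jsd),
                        gaze_right_x = 0.5 + p$scanpath$disparity / 2 +
                          stats::rnorm(length(tg), 0, jsd),
                        gaze_right_y = 0.5 + stats::rnorm(length(tg), 0, jsd))
      onset <- onset + p$gap_ms
      delta <- if (noise) stats::rnorm(1) else 0
      mouth_shift <- p$scanpath$pref_shift_sd * delta
      amps <- pu$amp_mu + ge +
        c(pu$coupling_a1_mouth * delta, 0, 0) +
        if (noise) stats::rnorm(3, 0, pu$amp_sd) else c(0, 0, 0)
      sp <- simulate_scanpath(grp, emo, rects, p, mouth_shift,
                              jitter_sd = jsd)
      pt <- simulate_pupil_trace(sp$gaze$t, amps, baseline, eye_offset, p,
                                 noise = noise)
      tr <- cbind(data.frame(t = onset + sp$gaze$t),
                  pt, sp$gaze[, -1])
      trials_rows[[paste(pid, k)]] <- data.frame(
        participant_id = pid, group = grp, emotion = emo, actor = actor,
        stimulus = stim, trial_index = k, onset = onset,
        offset = onset + p$trial_ms, stringsAsFactors = FALSE)
      truth_tr[[paste(pid, k, sep = ".")]] <- list(
        amplitudes = amps, mouth_shift = mouth_shift, delta = delta,
        baseline = baseline, fixations = sp$fixations)
      onset <- onset + p$trial_ms
      parts[[length(parts) + 1]] <- gap
      parts[[length(parts) + 1]] <- tr
    }
    st <- do.call(rbind, parts)
    st <- st[, .stream_cols]
    art <- list(blink = integer(0), spike = integer(0), drift = integer(0))
    if (artifacts) {
      inj <- inject_artifacts(st, p$artifacts$blink_per_min,
                              p$artifacts$spike_per_min,
                              p$artifacts$drift_per_min)
      st <- inj$stream
      art <- inj$truth
    }
    st$onscreen <- .onscreen_flag(st)
    class(st) <- c("sample_stream", "data.frame")
    streams[[pid]] <- st
    truth_art[[pid]] <- art
  }
  trials <- do.call(rbind, trials_rows)
  rownames(trials) <- NULL
  list(streams = streams, trials = trials, participants = participants,
       aoi_map = aoi_map,
       truth = list(trials = truth_tr, artifacts = truth_art,
                    windows = true_component_windows(p), seed = seed),
       params = p, seed = seed)
}

#' Fast truth-path generator for bin-level looking time
#'
#' For power and calibration studies: generates scanpath truth segments for
#' a full design and converts them directly to per-trial, per-AOI 50 ms bin
#' counts (samples labelled by the true segment AOI), bypassing sample
#' emission, gaze jitter and detection. Identical in distribution to
#' running [bin_looking_time()] on jitter-free simulated samples.
#'
#' @param params simulation parameters.
#' @param seed integer seed.
#' @param bin_ms bin width (default 50).
#' @param window_start,window_end analysis window (ms).
#' @param null_groups if TRUE both groups use the TD preference functions
#'   (null generator for type-I calibration).
#' @return `data.frame`: `participant_id`, `group`, `emotion`,
#'   `trial_index`, `aoi` (eyes/mouth), `bin`, `time`, `count`, plus
#'   participant covariates `age`, `sex`, `onscreen_time`.
#' @export
sim_looking_bins <- function(params = sim_params(), seed = 1, bin_ms = 50,
                             window_start = 500, window_end = 4500,
                             null_groups = FALSE) {
  set.seed(seed)
  p <- params
  if (null_groups) p$scanpath$prefs$ASD <- p$scanpath$prefs$TD
  dt <- 1000 / p$rate_hz
  n_bins <- (window_end - window_start) %/% bin_ms
  groups <- rep(c("ASD", "TD"), each = p$n_per_group)
  ids <- sprintf("P%03d", seq_along(groups))
  rects <- default_aoi_map("s")[["s"]]
  t_grid <- seq(0, p$trial_ms - dt / 2, by = dt)
  in_win <- t_grid >= window_start & t_grid < window_end
  bin_of <- pmin(floor((t_grid[in_win] - window_start) / bin_ms), n_bins - 1)
  age <- round(stats::runif(length(ids), 20, 60))
  sex <- sample(c("male", "female"), length(ids), replace = TRUE)
  onscreen <- pmin(1, pmax(0.5, stats::rnorm(length(ids), 0.82, 0.08)))
  tw <- t_grid[in_win]
  n_cells <- n_bins * 2L
  n_units <- length(ids) * p$n_trials
  counts <- matrix(0L, n_units, n_cells)
  emo_v <- character(n_units); pid_i <- integer(n_units)
  trial_v <- integer(n_units); delta_v <- numeric(n_units)
  u <- 0L
  for (i in seq_along(ids)) {
    for (k in seq_len(p$n_trials)) {
      u <- u + 1L
      emo <- sample(p$emotions, 1)
      delta_v[u] <- stats::rnorm(1)
      mouth_shift <- p$scanpath$pref_shift_sd * delta_v[u]
      seg <- .scanpath_segments(groups[i], emo, rects, p, mouth_shift)
      cell <- integer(0)
      for (s in seg) {
        if (s$kind != "fixation" || !(s$aoi %in% c("eyes", "mouth"))) next
        lo <- findInterval(s$onset - 1e-9, tw) + 1L
        hi <- findInterval(s$offset - 1e-9, tw)
        if (hi < lo) next
        aoi_id <- if (s$aoi == "eyes") 0L else 1L
        cell <- c(cell, bin_of[lo:hi] * 2L + aoi_id + 1L)
      }
      if (length(cell) > 0)
        counts[u, ] <- tabulate(cell, nbins = n_cells)
      emo_v[u] <- emo; pid_i[u] <- i; trial_v[u] <- k
    }
  }
  res <- data.frame(
    participant_id = rep(ids[pid_i], each = n_cells),
    group = rep(groups[pid_i], each = n_cells),
    emotion = rep(emo_v, each = n_cells),
    trial_index = rep(trial_v, each = n_cells),
    bin = rep(rep(0:(n_bins - 1), each = 2L), n_units),
    aoi = rep(c("eyes", "mouth"), n_bins * n_units),
    count = as.integer(t(counts)),
    age = rep(age[pid_i], each = n_cells),
    sex = rep(sex[pid_i], each = n_cells),
    onscreen_time = rep(onscreen[pid_i], each = n_cells),
    stringsAsFactors = FALSE)
  res$time <- window_start + res$bin * bin_ms
  # per-trial truth (the mouth-preference deviation drives the pupil
  # coupling in the full generator)
  attr(res, "trial_info") <- data.frame(
    participant_id = ids[pid_i], group = groups[pid_i], emotion = emo_v,
    trial_index = trial_v, delta = delta_v, age = age[pid_i],
    sex = sex[pid_i], onscreen_time = onscreen[pid_i],
    stringsAsFactors = FALSE)
  res
}

#' Simulate bin-level looking time with a polynomial time course
#'
#' Direct generator for degree-selection checks: bin means follow a given
#' polynomial in (scaled) time plus Gaussian noise, with a participant
#' random intercept.
#'
#' @param coefs polynomial coefficients over scaled time in `[-1, 1]`
#'   (constant first); e.g. `c(8, 2, 0, 1.5)` is a cubic course.
#' @param n_participants,n_trials design size.
#' @param n_bins bins per trial.
#' @param sd_noise residual SD; `sd_participant` random-intercept SD.
#' @param seed integer seed.
#' @return `data.frame`: `participant_id`, `trial_index`, `bin`, `time`
#'   (scaled), `count`.
#' @export
simulate_polynomial_bins <- function(coefs, n_participants = 60,
                                     n_trials = 2, n_bins = 16,
                                     sd_noise = 2, sd_participant = 1,
                                     seed = 1) {
  set.seed(seed)
  tt <- seq(-1, 1, length.out = n_bins)
  mu <- as.numeric(outer(tt, seq_along(coefs) - 1, "^") %*% coefs)
  rows <- list()
  for (i in seq_len(n_participants)) {
    ri <- stats::rnorm(1, 0, sd_participant)
    for (k in seq_len(n_trials)) {
      rows[[paste(i, k)]] <- data.frame(
        participant_id = sprintf("P%03d", i), trial_index = k,
        bin = seq_len(n_bins) - 1, time = tt,
        count = mu + ri + stats::rnorm(n_bins, 0, sd_noise))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
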