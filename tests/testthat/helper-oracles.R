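# Independent brute-force re-implementations of every pupil filter and the
# looking-time binner, written as plain loops straight from the filter
# definitions. They share no code with the package internals and serve as
# oracles in equivalence tests.

mad_raw_oracle <- function(x) {
  x <- x[!is.na(x)]
  median(abs(x - median(x)))
}

MAD_FLOOR_MM <- 0.002   # instrument diameter-quantization floor

oracle_size_filter <- function(x, min_mm = 2, max_mm = 8) {
  for (i in seq_along(x))
    if (!is.na(x[i]) && (x[i] < min_mm || x[i] > max_mm)) x[i] <- NA
  x
}

oracle_speed_filter <- function(t, x, k = 3) {
  n <- length(x)
  if (sum(!is.na(x)) < 3) return(x)
  speed <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    sb <- sf <- NA
    for (j in rev(seq_len(i - 1))) if (!is.na(x[j])) {
      sb <- abs(x[i] - x[j]) / (t[i] - t[j]); break
    }
    for (j in seq_len(n)[-seq_len(i)]) if (!is.na(x[j])) {
      sf <- abs(x[j] - x[i]) / (t[j] - t[i]); break
    }
    speed[i] <- max(c(sb, sf), na.rm = TRUE)
    if (is.infinite(speed[i])) speed[i] <- NA
  }
  med <- median(speed, na.rm = TRUE)
  thr <- med + k * max(mad_raw_oracle(speed), MAD_FLOOR_MM / median(diff(t)))
  for (i in seq_len(n))
    if (!is.na(speed[i]) && speed[i] > thr) x[i] <- NA
  x
}

# missing runs as (start, end, prev, nxt) with duration = missing-time span
oracle_runs <- function(t, x) {
  dt <- median(diff(t))
  runs <- list()
  i <- 1
  while (i <= length(x)) {
    if (is.na(x[i])) {
      j <- i
      while (j < length(x) && is.na(x[j + 1])) j <- j + 1
      prev <- if (i > 1) i - 1 else NA
      nxt <- if (j < length(x)) j + 1 else NA
      dur <- if (is.na(prev) || is.na(nxt)) NA else t[nxt] - t[prev] - dt
      runs[[length(runs) + 1]] <- list(start = i, end = j, prev = prev,
                                       nxt = nxt, duration = dur)
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

oracle_blink_margins <- function(t, x, gap_min = 75, gap_max = 250,
                                 margin = 25) {
  out <- x
  for (r in oracle_runs(t, x)) {
    if (is.na(r$duration) || r$duration <= gap_min || r$duration > gap_max)
      next
    for (i in seq_along(x)) {
      if (t[i] >= t[r$prev] - margin - 1e-6 && t[i] <= t[r$prev] + 1e-6)
        out[i] <- NA
      if (t[i] >= t[r$nxt] - 1e-6 && t[i] <= t[r$nxt] + margin + 1e-6)
        out[i] <- NA
    }
  }
  out
}

oracle_moving_mean <- function(t, x, half) {
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    inwin <- which(abs(t - t[i]) <= half + 1e-6 & !is.na(x))
    if (length(inwin) > 0) out[i] <- mean(x[inwin])
  }
  out
}

oracle_trend_filter <- function(t, x, k = 3, span_ms = 250) {
  for (pass in 1:2) {
    if (all(is.na(x))) return(x)
    trend <- oracle_moving_mean(t, x, span_ms / 2)
    resid <- x - trend
    med <- median(resid, na.rm = TRUE)
    thr <- k * max(mad_raw_oracle(resid), MAD_FLOOR_MM)
    for (i in seq_along(x))
      if (!is.na(resid[i]) && abs(resid[i] - med) > thr) x[i] <- NA
  }
  x
}

oracle_combine <- function(left, right) {
  both <- which(!is.na(left) & !is.na(right))
  offset <- if (length(both) > 0) mean(left[both] - right[both]) else 0
  out <- rep(NA_real_, length(left))
  for (i in seq_along(left)) {
    l <- left[i]; r <- right[i]
    if (is.na(l) && !is.na(r)) l <- r + offset
    if (is.na(r) && !is.na(left[i])) r <- left[i] - offset
    if (!is.na(l) && !is.na(r)) out[i] <- (l + r) / 2
  }
  out
}

oracle_interp <- function(t, x, max_gap = 300) {
  for (r in oracle_runs(t, x)) {
    if (is.na(r$duration) || r$duration > max_gap + 1e-6) next
    for (i in r$start:r$end)
      x[i] <- x[r$prev] + (x[r$nxt] - x[r$prev]) *
        (t[i] - t[r$prev]) / (t[r$nxt] - t[r$prev])
  }
  x
}

oracle_smooth <- function(t, x, span = 30) {
  out <- oracle_moving_mean(t, x, span / 2)
  out[is.na(x)] <- NA
  out
}

oracle_bin_counts <- function(t, x, y, rects, bin_ms = 50, w0 = 500,
                              w1 = 4500) {
  n_bins <- (w1 - w0) / bin_ms
  labs <- c("eyes", "mouth", "other", "offscreen")
  counts <- matrix(0L, n_bins, 4, dimnames = list(NULL, labs))
  for (i in seq_along(t)) {
    if (t[i] < w0 || t[i] >= w1) next
    b <- floor((t[i] - w0) / bin_ms) + 1
    lab <- "offscreen"
    if (!is.na(x[i]) && !is.na(y[i]) && x[i] >= 0 && x[i] <= 1 &&
        y[i] >= 0 && y[i] <= 1) {
      lab <- "other"
      for (nm in c("eyes", "mouth")) {
        r <- rects[[nm]]
        if (x[i] >= r[1] && x[i] < r[1] + r[3] &&
            y[i] >= r[2] && y[i] < r[2] + r[4]) lab <- nm
      }
    }
    counts[b, lab] <- counts[b, lab] + 1L
  }
  counts
}

# random 50-sample pupil trace on a 300 Hz grid with missing runs
random_trace <- function(n = 50, p_na = 0.15) {
  t <- (seq_len(n) - 1) * 1000 / 300
  x <- 4 + cumsum(rnorm(n, 0, 0.02)) + rnorm(n, 0, 0.05)
  drop <- rbinom(n, 1, p_na) == 1
  if (runif(1) < 0.5) {  # occasionally a longer run
    s <- sample(n - 8, 1)
    drop[s:(s + sample(3:8, 1))] <- TRUE
  }
  x[drop] <- NA
  list(t = t, x = x)
}

# temporal-overlap matching of detected events against truth (one-to-one,
# greedy in truth order; a pair matches when the overlap covers at least
# half of the shorter event)
match_fixations <- function(truth, detected) {
  used <- rep(FALSE, nrow(detected))
  hits <- 0
  for (i in seq_len(nrow(truth))) {
    if (nrow(detected) == 0) break
    ov <- pmin(truth$offset[i], detected$offset) -
      pmax(truth$onset[i], detected$onset)
    ok <- which(!used & ov >= 0.5 * pmin(truth$duration[i],
                                         detected$duration))
    if (length(ok) > 0) {
      used[ok[1]] <- TRUE
      hits <- hits + 1
    }
  }
  c(hits = hits, n_truth = nrow(truth), n_detected = nrow(detected))
}

# Truth-side detectability at zero noise: a saccade whose peak angular
# velocity lies below the converged threshold cannot separate its flanking
# fixations, so such truth events merge. Saccades near the threshold are
# ambiguous; trials containing one are reported so exactness checks can
# fall back to bracketing. Peak velocity of the cosine ramp of amplitude d
# over duration T is d * pi / (2 T).
detectable_truth <- function(fixations, threshold, geom = gaze_params(),
                             saccade_ms = 30, min_dur = 100,
                             max_dur = 2500, erosion = 8 * 1000 / 300) {
  fx <- fixations[order(fixations$onset), ]
  merged <- fx[1, ]
  ambiguous <- FALSE
  for (i in seq_len(nrow(fx) - 1)) {
    dx <- (fx$x[i + 1] - fx$x[i]) * geom$screen_w_m
    dy <- (fx$y[i + 1] - fx$y[i]) * geom$screen_h_m
    vp <- sqrt(dx^2 + dy^2) * pi / 2 / (saccade_ms / 1000) /
      geom$viewing_distance_m * 180 / pi
    j <- nrow(merged)
    if (vp < 0.7 * threshold) {
      merged$offset[j] <- fx$offset[i + 1]
      merged$duration[j] <- merged$offset[j] - merged$onset[j]
    } else {
      if (vp < 3 * threshold) ambiguous <- TRUE
      merged <- rbind(merged, fx[i + 1, ])
    }
  }
  keep_lo <- merged$duration >= min_dur + erosion & merged$duration <= max_dur
  keep_hi <- merged$duration >= min_dur & merged$duration <= max_dur
  list(events = merged[keep_lo, ], n_lo = sum(keep_lo), n_hi = sum(keep_hi),
       ambiguous = ambiguous ||
         any(merged$duration > min_dur & merged$duration < min_dur + erosion))
}

# bare trial data.frame from a simulated scanpath (always-onscreen gaze)
scanpath_trial <- function(sp) {
  trial <- cbind(data.frame(t = sp$gaze$t), sp$gaze[, -1])
  trial$pupil_left <- 4; trial$pupil_right <- 4
  trial$onscreen <- TRUE
  trial
}
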