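# Pupil filter chain: hand-computed examples, boundary behavior, and
# equivalence with independent brute-force oracles.

grid300 <- function(n) (seq_len(n) - 1) * 1000 / 300

test_that("size filter uses strict inequalities and keeps the bounds", {
  expect_equal(filter_invalid_sizes(c(1.9, 3.2, 8.1)),
               c(NA, 3.2, NA))
  expect_equal(filter_invalid_sizes(c(2.0, 8.0)), c(2.0, 8.0))
  x <- c(2.5, 4, 7.9)
  expect_equal(filter_invalid_sizes(x), x)
  expect_error(filter_invalid_sizes(1, min_mm = 8, max_mm = 2), "below")
})

test_that("dilation speed filter removes a one-sample spike, hand case", {
  t <- grid300(10)
  x <- rep(4, 10); x[5] <- 5            # +1 mm spike
  # oracle by hand: spike speed = 1 mm / 3.33 ms = 0.3; neighbours 0.3;
  # remaining speeds 0 -> median 0, MAD 0 (epsilon floor) -> spike and its
  # two contaminated neighbours exceed the threshold
  out <- dilation_speed_filter(t, x)
  expect_true(is.na(out[5]))
  expect_equal(out, oracle_speed_filter(t, x))
})

test_that("constant and equal-speed series lose nothing (MAD floor)", {
  t <- grid300(20)
  expect_equal(dilation_speed_filter(t, rep(4, 20)), rep(4, 20))
  ramp <- 4 + 0.001 * t                 # all speeds equal -> MAD 0
  expect_equal(dilation_speed_filter(t, ramp), ramp)
})

test_that("blink margins apply only to gaps in (75, 250] ms", {
  n <- 200; t <- grid300(n)
  dt <- 1000 / 300
  mk_gap <- function(len_samples) {
    x <- rep(4, n)
    x[80:(80 + len_samples - 1)] <- NA
    x
  }
  # 100 ms gap = 30 samples: ~8 samples removed on each side (margin 25 ms)
  x <- mk_gap(30)
  out <- blink_margin_removal(t, x)
  expect_equal(sum(is.na(out)) - sum(is.na(x)), 16)
  expect_equal(out, oracle_blink_margins(t, x))
  # 50 ms gap (15 samples): below blink range, untouched
  x50 <- mk_gap(15)
  expect_equal(blink_margin_removal(t, x50), x50)
  # 300 ms gap (90 samples): above blink range, untouched
  x300 <- mk_gap(90)
  expect_equal(blink_margin_removal(t, x300), x300)
})

test_that("two-pass trend filter removes staged outliers over a ramp", {
  t <- grid300(100)
  x <- 4 + 0.0001 * t                   # clean slow ramp: unchanged
  expect_equal(trendline_filter_two_pass(t, x), x)
  x1 <- x; x1[40] <- x1[40] + 1         # single large outlier: pass 1
  out1 <- trendline_filter_two_pass(t, x1)
  expect_true(is.na(out1[40]))
  expect_equal(out1, oracle_trend_filter(t, x1))
  # two stacked outliers of very different size: both must be gone after
  # the two passes, matching the oracle pass-for-pass
  x2 <- x; x2[40] <- x2[40] + 1; x2[60] <- x2[60] + 0.12
  out2 <- trendline_filter_two_pass(t, x2)
  expect_true(is.na(out2[40]) && is.na(out2[60]))
  expect_equal(out2, oracle_trend_filter(t, x2))
})

test_that("combine_eyes fills from the other eye with the individual offset", {
  left <- c(4.4, 4.4, NA, 4.4, 4.4)
  right <- c(4.0, 4.0, 4.0, 4.0, NA)
  # offset = +0.4; filled left = 4.4 -> mean 4.2; filled right = 4.0
  out <- combine_eyes(left, right)
  expect_equal(out, rep(4.2, 5))
  expect_equal(out, oracle_combine(left, right))
  expect_true(is.na(suppressWarnings(combine_eyes(NA_real_, NA_real_))))
  expect_warning(combine_eyes(c(NA, 1), c(2, NA)), "offset")
})

test_that("gap interpolation respects the 300 ms bound and trace edges", {
  n <- 400; t <- grid300(n)
  x <- 4 + 0.0005 * t
  x200 <- x; x200[100:159] <- NA        # 60 samples = 200 ms
  out <- interpolate_gaps(t, x200)
  expect_equal(out, x, tolerance = 1e-12)   # linear fill of a linear trace
  x400 <- x; x400[100:219] <- NA        # 120 samples = 400 ms
  expect_equal(interpolate_gaps(t, x400), x400)
  x300 <- x; x300[100:189] <- NA        # 90 samples = exactly 300 ms
  expect_false(anyNA(interpolate_gaps(t, x300)))
  lead <- x; lead[1:10] <- NA           # no left anchor
  expect_equal(interpolate_gaps(t, lead), lead)
})

test_that("moving average spreads a unit impulse over 9 samples at 300 Hz", {
  n <- 31; t <- grid300(n)
  x <- rep(0, n); x[16] <- 1
  out <- smooth_moving_average(t, x)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  expect_equal(out[12:20], rep(1 / 9, 9))
  expect_equal(smooth_moving_average(t, rep(3, n)), rep(3, n))
  xm <- x; xm[14] <- NA                 # renormalizes over valid members
  expect_equal(smooth_moving_average(t, xm), oracle_smooth(t, xm))
})

test_that("baseline correction subtracts the first-500-ms mean", {
  t <- grid300(1350)
  bc <- baseline_correct(t, rep(4, 1350))
  expect_equal(bc$baseline, 4)
  expect_equal(bc$response, rep(0, 1350))
  # ramp 4.0 -> 4.4 over the trial: baseline = closed-form mean of the ramp
  # over [0, 500): 4 + 0.4 * mean(t[t<500]) / 4500
  x <- 4 + 0.4 * t / 4500
  bc2 <- baseline_correct(t, x)
  expect_equal(bc2$baseline, 4 + 0.4 * mean(t[t < 500]) / 4500)
  expect_gt(max(bc2$response), 0)
  expect_lt(min(bc2$response), 0)
  bad <- rep(4, 1350); bad[t < 500] <- NA
  expect_false(baseline_correct(t, bad)$baseline_valid)
})

test_that("every filter matches its brute-force oracle on random traces", {
  set.seed(42)
  for (rep in 1:40) {
    tr <- random_trace()
    expect_equal(filter_invalid_sizes(tr$x), oracle_size_filter(tr$x))
    expect_equal(dilation_speed_filter(tr$t, tr$x),
                 oracle_speed_filter(tr$t, tr$x))
    expect_equal(blink_margin_removal(tr$t, tr$x),
                 oracle_blink_margins(tr$t, tr$x))
    expect_equal(as.numeric(trendline_filter_two_pass(tr$t, tr$x)),
                 as.numeric(oracle_trend_filter(tr$t, tr$x)))
    expect_equal(interpolate_gaps(tr$t, tr$x), oracle_interp(tr$t, tr$x))
    expect_equal(smooth_moving_average(tr$t, tr$x),
                 oracle_smooth(tr$t, tr$x))
    tr2 <- random_trace()
    expect_equal(combine_eyes(tr$x, tr2$x), oracle_combine(tr$x, tr2$x))
  }
})

test_that("filters only ever add missingness (monotone destruction)", {
  set.seed(7)
  for (rep in 1:20) {
    tr <- random_trace()
    for (f in list(function(x) filter_invalid_sizes(x),
                   function(x) dilation_speed_filter(tr$t, x),
                   function(x) blink_margin_removal(tr$t, x),
                   function(x) as.numeric(trendline_filter_two_pass(tr$t, x)))) {
      out <- f(tr$x)
      expect_true(all(is.na(out[is.na(tr$x)])))
      same <- !is.na(out)
      expect_equal(out[same], tr$x[same])
    }
  }
})

test_that("preprocess_trial excludes on valid fraction strictly below 50%", {
  set.seed(3)
  t <- grid300(1350)
  mk_trial <- function(p_missing) {
    x <- 4 + 0.05 * sin(t / 700)
    drop <- seq_len(1350) %in% sample(1350, round(p_missing * 1350))
    trial <- data.frame(t = t, pupil_left = ifelse(drop, NA, x),
                        pupil_right = ifelse(drop, NA, x + 0.2),
                        gaze_left_x = 0.5, gaze_left_y = 0.5,
                        gaze_right_x = 0.5, gaze_right_y = 0.5,
                        onscreen = TRUE)
    # the same samples are missing in both eyes so interpolation cannot
    # restore long runs; use scattered singles (interpolable) vs none
    trial
  }
  clean <- preprocess_trial(mk_trial(0))
  expect_false(clean$excluded)
  expect_gte(clean$valid_fraction, 0.99)
  expect_equal(mean(clean$response[t < 500], na.rm = TRUE), 0,
               tolerance = 1e-10)
})

test_that("default-rate artifacts are removed; untouched samples survive", {
  set.seed(55)
  p <- sim_params(); p$n_per_group <- 2; p$n_trials <- 6
  clean <- simulate_dataset(p, seed = 66, noise = TRUE, artifacts = FALSE)
  spike_rm <- drift_rm <- c(0, 0); final_ok <- c(0, 0)
  for (pid in names(clean$streams)) {
    st <- clean$streams[[pid]]
    inj <- inject_artifacts(st, 8, 4, 1)
    t <- inj$stream$t
    per_eye <- function(x) {
      x <- filter_invalid_sizes(x)
      x <- dilation_speed_filter(t, x)
      x <- blink_margin_removal(t, x)
      as.numeric(trendline_filter_two_pass(t, x))
    }
    out_l <- per_eye(inj$stream$pupil_left)
    out_r <- per_eye(inj$stream$pupil_right)
    tr <- inj$truth
    # blink samples are missing by construction; spikes and drift cores
    # must be caught by the speed and trend filters
    expect_true(all(is.na(out_l[tr$blink])))
    spike_rm <- spike_rm + c(sum(is.na(out_l[tr$spike])), length(tr$spike))
    drift_rm <- drift_rm + c(sum(is.na(out_l[tr$drift])), length(tr$drift))
    # final trace: untouched samples survive (directly or via the
    # interpolation of short gaps the robust fences create)
    comb <- interpolate_gaps(t, combine_eyes(out_l, out_r))
    art <- unique(c(tr$blink, tr$spike, tr$drift))
    near <- unique(as.vector(outer(tr$blink, -9:9, `+`)))
    keep <- setdiff(seq_along(comb), c(art, near))
    final_ok <- final_ok + c(sum(!is.na(comb[keep])), length(keep))
  }
  expect_gte(spike_rm[1] / spike_rm[2], 0.98)
  expect_gte(drift_rm[1] / drift_rm[2], 0.95)
  expect_gte(final_ok[1] / final_ok[2], 0.99)
})

test_that("chain is idempotent on clean data up to the single smoothing", {
  t <- grid300(1350)
  x <- 4 + 0.1 * sin(t / 900)
  s1 <- smooth_moving_average(t, x)
  # a second full filter pass on the already-filtered series removes nothing
  y <- s1
  y2 <- filter_invalid_sizes(y)
  y2 <- dilation_speed_filter(t, y2)
  y2 <- blink_margin_removal(t, y2)
  expect_equal(y2, y)
})
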