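# AOI assignment, looking-time binning, fixation outcomes, covariates.

map1 <- default_aoi_map("s")
r_eyes <- map1$s$eyes
r_mouth <- map1$s$mouth

test_that("assign_aoi applies inclusive/exclusive edge rules", {
  cx <- r_eyes[1] + r_eyes[3] / 2
  cy <- r_eyes[2] + r_eyes[4] / 2
  expect_equal(as.character(assign_aoi(cx, cy, map1, "s")), "eyes")
  # left/top edges belong to the rectangle, right/bottom do not
  expect_equal(as.character(assign_aoi(r_eyes[1], r_eyes[2], map1, "s")),
               "eyes")
  expect_equal(as.character(assign_aoi(r_eyes[1] + r_eyes[3], cy, map1, "s")),
               "other")
  # the eyes' bottom edge at y = eyes_y1 is outside eyes; with the default
  # map geometry it lies between the rectangles -> other
  expect_equal(as.character(assign_aoi(cx, r_eyes[2] + r_eyes[4], map1, "s")),
               "other")
  expect_equal(as.character(assign_aoi(1.2, 0.5, map1, "s")), "offscreen")
  expect_equal(as.character(assign_aoi(NA, 0.5, map1, "s")), "offscreen")
  expect_error(assign_aoi(0.5, 0.5, map1, "nope"), "not in AOI map")
})

make_trial <- function(x, y, n = 1350) {
  t <- (seq_len(n) - 1) * 1000 / 300
  trial <- data.frame(t = t, pupil_left = 4, pupil_right = 4,
                      gaze_left_x = x, gaze_left_y = y,
                      gaze_right_x = x, gaze_right_y = y, onscreen = TRUE)
  attr(trial, "meta") <- data.frame(participant_id = "P1", trial_index = 1,
                                    group = "TD", emotion = "happy",
                                    stimulus = "s")
  trial
}

test_that("bin counts are 15 per 50 ms bin at 300 Hz for constant gaze", {
  trial <- make_trial(r_eyes[1] + 0.1, r_eyes[2] + 0.1)
  b <- bin_looking_time(trial, map1)
  expect_equal(nrow(b), 80 * 4)
  eyes <- b[b$aoi == "eyes", ]
  expect_equal(nrow(eyes), 80)
  expect_true(all(eyes$count == 15))
  expect_true(all(b$count[b$aoi != "eyes"] == 0))
  expect_error(bin_looking_time(trial, map1, bin_ms = 33), "divide")
})

test_that("offscreen trials yield offscreen-only counts", {
  trial <- make_trial(NA_real_, NA_real_)
  trial$onscreen <- FALSE
  b <- suppressWarnings(bin_looking_time(trial, map1))
  expect_true(all(b$count[b$aoi == "offscreen"] == 15))
  expect_true(all(b$count[b$aoi != "offscreen"] == 0))
})

test_that("bin counts conserve samples and match the brute-force oracle", {
  set.seed(15)
  p <- sim_params()
  for (r in 1:5) {
    sp <- simulate_scanpath("ASD", "happy", map1$s, p)
    trial <- scanpath_trial(sp)
    attr(trial, "meta") <- data.frame(participant_id = "P", trial_index = r,
                                      group = "ASD", emotion = "happy",
                                      stimulus = "s")
    b <- bin_looking_time(trial, map1)
    g <- combine_gaze(trial)
    oracle <- oracle_bin_counts(g$t, g$x, g$y, map1$s)
    got <- matrix(b$count[order(b$aoi, b$bin)], ncol = 4,
                  dimnames = list(NULL, sort(c("eyes", "mouth", "other",
                                               "offscreen"))))
    for (lab in colnames(oracle))
      expect_equal(as.numeric(got[, lab]), as.numeric(oracle[, lab]))
    # conservation: per bin the labels sum to the nominal sample count
    tot <- tapply(b$count, b$bin, sum)
    expect_true(all(tot == 15))
  }
})

test_that("broadening bins to 100/200 ms preserves totals exactly", {
  set.seed(16)
  sp <- simulate_scanpath("TD", "fear", map1$s, sim_params())
  trial <- scanpath_trial(sp)
  attr(trial, "meta") <- data.frame(participant_id = "P", trial_index = 1,
                                    group = "TD", emotion = "fear",
                                    stimulus = "s")
  b50 <- bin_looking_time(trial, map1, 50)
  for (bw in c(100, 200)) {
    bb <- bin_looking_time(trial, map1, bw)
    for (lab in c("eyes", "mouth", "other", "offscreen")) {
      expect_equal(sum(bb$count[bb$aoi == lab]),
                   sum(b50$count[b50$aoi == lab]))
      # each broad bin equals the sum of its constituent 50 ms bins
      fine <- b50[b50$aoi == lab, ]
      agg <- tapply(fine$count, fine$bin %/% (bw / 50), sum)
      expect_equal(as.numeric(bb$count[bb$aoi == lab]), as.numeric(agg))
    }
  }
})

test_that("fixation outcomes aggregate counts and mean durations per AOI", {
  mk_ev <- function(aoi, dur) {
    ev <- data.frame(onset = cumsum(c(0, dur))[seq_along(dur)],
                     offset = cumsum(dur), duration = dur,
                     x = rep(0.5, length(dur)), y = rep(0.5, length(dur)),
                     aoi = factor(aoi, levels = c("eyes", "mouth", "other",
                                                  "offscreen")))
    attr(ev, "meta") <- data.frame(participant_id = "P1", trial_index = 1,
                                   group = "TD", emotion = "happy",
                                   stimulus = "s")
    ev
  }
  ev <- mk_ev(c("eyes", "eyes", "eyes", "mouth"), c(200, 300, 400, 150))
  out <- fixation_outcomes(list(T1 = ev))
  eyes <- out[out$aoi == "eyes", ]
  expect_equal(eyes$n_fixations, 3)
  expect_equal(eyes$mean_duration, 300)
  mouth <- out[out$aoi == "mouth", ]
  expect_equal(mouth$n_fixations, 1)
  # trial without fixations: no rows, flagged
  empty <- mk_ev(character(0), numeric(0))
  out2 <- fixation_outcomes(list(T1 = ev, T2 = empty))
  expect_equal(attr(out2, "no_fixation_trials"), "T2")
  expect_equal(nrow(out2), 2)
  # AOI with zero fixations: count 0, undefined mean
  only_eyes <- mk_ev("eyes", 250)
  out3 <- fixation_outcomes(list(T1 = only_eyes))
  expect_equal(out3$n_fixations[out3$aoi == "mouth"], 0)
  expect_true(is.na(out3$mean_duration[out3$aoi == "mouth"]))
})

test_that("covariates: onscreen fraction and centered gaze deviation", {
  n <- 300
  st <- data.frame(t = (0:(n - 1)) * 10, pupil_left = 4, pupil_right = 4,
                   gaze_left_x = 0.5, gaze_left_y = 0.5,
                   gaze_right_x = 0.5, gaze_right_y = 0.5)
  cov <- compute_covariates(st)
  expect_equal(cov$onscreen_time, 1)
  expect_equal(cov$gaze_deviation, 0)
  st2 <- st
  st2$gaze_left_x[1:150] <- NA; st2$gaze_right_x[1:150] <- NA
  st2$gaze_left_y[1:150] <- NA; st2$gaze_right_y[1:150] <- NA
  expect_equal(compute_covariates(st2)$onscreen_time, 0.5)
  # gaze pinned at a screen corner: deviation = sqrt(0.5^2 + 0.5^2)
  st3 <- st
  st3$gaze_left_x <- 0; st3$gaze_right_x <- 0
  st3$gaze_left_y <- 0; st3$gaze_right_y <- 0
  expect_equal(compute_covariates(st3)$gaze_deviation, sqrt(0.5),
               tolerance = 1e-12)
  expect_error(compute_covariates(st[0, ]), "empty")
})
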