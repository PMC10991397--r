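# Mixed-model layer: fitting contracts, scaling invariance, degree
# comparison, Tukey contrasts, association models.

set.seed(30)
toy <- local({
  # small two-group trial-level dataset with a known group x aoi effect
  n <- 24
  pid <- rep(sprintf("P%02d", 1:n), each = 6)
  grp <- rep(rep(c("ASD", "TD"), each = n / 2), each = 6)
  aoi <- rep(c("eyes", "mouth"), n * 3)
  emo <- rep(rep(c("fear", "happy", "neutral"), each = 2), n)
  mu <- ifelse(aoi == "eyes" & grp == "ASD", -1, 0)
  data.frame(participant_id = pid, group = grp, aoi = aoi, emotion = emo,
             y = mu + rep(rnorm(n, 0, 0.5), each = 6) + rnorm(n * 6, 0, 0.7),
             age = rep(round(runif(n, 20, 60)), each = 6),
             sex = rep(sample(c("male", "female"), n, TRUE), each = 6),
             onscreen_time = rep(runif(n, 0.6, 1), each = 6))
})

test_that("fit_lmm returns coefficients with bracketing CIs and F tests", {
  mr <- fit_lmm(y ~ group * aoi + age + sex + onscreen_time +
                  (1 | participant_id),
                toy, scale_vars = c("y", "age", "onscreen_time"))
  expect_s3_class(mr, "model_result")
  expect_true(all(mr$coefficients$ci_lo <= mr$coefficients$estimate))
  expect_true(all(mr$coefficients$ci_hi >= mr$coefficients$estimate))
  expect_true(all(c("group", "aoi", "group:aoi") %in% mr$tests$term))
  expect_true(all(mr$tests$p.value >= 0 & mr$tests$p.value <= 1, na.rm = TRUE))
  # the injected group x aoi interaction is detected
  expect_lt(mr$tests$p.value[mr$tests$term == "group:aoi"], 0.01)
})

test_that("constant outcomes take the degenerate-fit error path", {
  bad <- toy; bad$y <- 1
  expect_error(fit_lmm(y ~ group + (1 | participant_id), bad), "degenerate")
})

test_that("rescaling a continuous covariate leaves all F tests unchanged", {
  mr1 <- fit_lmm(y ~ group * aoi + age + onscreen_time + (1 | participant_id),
                 toy, scale_vars = c("y", "age", "onscreen_time"))
  toy10 <- toy; toy10$age <- toy10$age * 10
  mr2 <- fit_lmm(y ~ group * aoi + age + onscreen_time + (1 | participant_id),
                 toy10, scale_vars = c("y", "age", "onscreen_time"))
  expect_equal(mr1$tests$statistic, mr2$tests$statistic, tolerance = 1e-8)
  expect_equal(mr1$tests$p.value, mr2$tests$p.value, tolerance = 1e-8)
})

test_that("Satterthwaite and asymptotic tests agree at large denominator df", {
  mr_s <- fit_lmm(y ~ group * aoi + (1 | participant_id), toy)
  mr_w <- fit_lmm(y ~ group * aoi + (1 | participant_id), toy,
                  ddf = "asymptotic")
  i <- mr_s$tests$term == "group:aoi"; j <- mr_w$tests$term == "group:aoi"
  # F with 1 num df ~ chi^2/1: statistics comparable, p-values close
  expect_equal(mr_s$tests$p.value[i], mr_w$tests$p.value[j],
               tolerance = 0.05)
})

test_that("posthoc contrasts count k(k-1)/2 and adjustment only raises p", {
  mr <- fit_lmm(y ~ emotion + (1 | participant_id), toy,
                scale_vars = "y")
  ct <- posthoc_contrasts(mr, ~ emotion)
  expect_equal(nrow(ct), 3)                  # C(3,2)
  ct_un <- posthoc_contrasts(mr, ~ emotion, adjust = "none")
  expect_true(all(ct$p.value >= ct_un$p.value - 1e-12))
  expect_error(posthoc_contrasts(mr, ~ emotion, at_times = c(1000)),
               "no time basis")
})

test_that("growth model drops single-level AOI with a warning", {
  b <- simulate_polynomial_bins(c(5, 1), n_participants = 20, seed = 31)
  b$count <- b$count
  b$aoi <- "eyes"; b$group <- rep(c("ASD", "TD"), length.out = nrow(b))
  expect_warning(growth_curve_model(b, degree = 1, ddf = "asymptotic"),
                 "single AOI")
})

test_that("degree comparison recommends the generating cubic degree", {
  b <- simulate_polynomial_bins(c(8, 2, 0, 1.5), seed = 32)
  tab <- compare_polynomial_degrees(b, max_degree = 4)
  expect_equal(nrow(tab), 5)
  expect_equal(attr(tab, "recommended"), 3)
  expect_true(all(diff(tab$logLik) > -1e-8))   # nested fits improve
  # pure-noise data: flat or linear recommendation in the large majority of
  # replicates (each spurious increment clears alpha = 0.05 by chance alone)
  rec0 <- sapply(1:10, function(s) {
    b0 <- simulate_polynomial_bins(c(5, 0), n_participants = 30, seed = 330 + s)
    attr(compare_polynomial_degrees(b0, max_degree = 3), "recommended")
  })
  expect_gte(mean(rec0 <= 1), 0.8)
  # max_degree = 1 gives the single-increment table
  expect_equal(nrow(compare_polynomial_degrees(b, max_degree = 1)), 2)
})

test_that("growth curve analysis recovers the injected crossing pattern", {
  b <- sim_looking_bins(seed = 34, bin_ms = 200)
  b$emotion <- NULL   # headline interaction only
  mr <- growth_curve_model(b, degree = 2, ddf = "asymptotic")
  i <- mr$tests$term == "ot1:group:aoi"
  expect_lt(mr$tests$p.value[i], 0.01)
  # sign: with sum contrasts (ASD = +1, eyes = +1), the ASD eye slope
  # exceeds the TD eye slope -> positive ot1:group:aoi coefficient
  co <- mr$coefficients
  expect_gt(co$estimate[co$term == "ot1:group1:aoi1"], 0)
  # post-hoc group contrasts on the 250 ms grid reproduce the crossing
  ct <- posthoc_contrasts(mr, ~ group | aoi, at_times = c(1000, 4250))
  eyes_early <- ct[ct$aoi == "eyes" & ct$time == 1000, ]
  eyes_late <- ct[ct$aoi == "eyes" & ct$time == 4250, ]
  expect_lt(eyes_early$estimate, 0)          # ASD - TD < 0 early on eyes
  expect_gt(eyes_late$estimate, 0)           # reversed late
})

test_that("null preferences center the polynomial interactions on null", {
  b <- sim_looking_bins(seed = 35, bin_ms = 200, null_groups = TRUE)
  b$emotion <- NULL
  mr <- growth_curve_model(b, degree = 1, ddf = "asymptotic",
                           random = "slope")
  i <- mr$tests$term == "ot1:group:aoi"
  expect_gt(mr$tests$p.value[i], 0.001)
})

test_that("association models recover the pupil-mouth coupling sign", {
  set.seed(36)
  # trial-level data with the generator's coupling logic: delta drives
  # mouth looking up and the early pupil amplitude down
  n <- 40; trials <- 10
  rows <- list(); pd_rows <- list(); out_rows <- list()
  for (i in 1:n) {
    pid <- sprintf("P%02d", i)
    for (k in 1:trials) {
      delta <- rnorm(1)
      pd1 <- 0.02 - 0.04 * delta + rnorm(1, 0, 0.01)
      mouth_look <- 5 + 2 * delta + rnorm(1, 0, 1)
      eyes_look <- 6 - 0.5 * delta + rnorm(1, 0, 1)
      key <- data.frame(participant_id = pid, trial_index = k,
                        group = "TD", emotion = sample(c("fear", "happy",
                                                         "neutral"), 1))
      pd_rows[[paste(i, k)]] <- cbind(key, pd_trc1 = pd1,
                                      pd_trc2 = 0, pd_trc3 = 0)
      for (aoi in c("eyes", "mouth")) {
        look <- if (aoi == "mouth") mouth_look else eyes_look
        out_rows[[paste(i, k, aoi)]] <- cbind(key, aoi = aoi,
                                              n_fixations = rpois(1, 8),
                                              mean_duration = rnorm(1, 300, 40))
        for (bin in 0:7)
          rows[[paste(i, k, aoi, bin)]] <- cbind(
            key, aoi = aoi, bin = bin, time = 500 + bin * 500,
            count = look + rnorm(1, 0, 0.5))
      }
    }
  }
  bins <- do.call(rbind, rows)
  pd <- do.call(rbind, pd_rows)
  outc <- do.call(rbind, out_rows)
  participants <- data.frame(participant_id = sprintf("P%02d", 1:n),
                             age = round(runif(n, 20, 60)),
                             sex = sample(c("male", "female"), n, TRUE),
                             onscreen_time = runif(n, 0.7, 1))
  win <- data.frame(component = paste0("T-RC", 1:3),
                    start_ms = c(500, 1000, 3000),
                    end_ms = c(1000, 3000, 4500))
  mods <- association_models(pd, outc, bins, win, participants,
                             ddf = "asymptotic")
  mouth1 <- mods$looking_trc1_mouth
  co <- mouth1$coefficients
  expect_lt(co$estimate[co$term == "pd_trc1"], 0)   # negative coupling
  i <- mouth1$tests$term == "pd_trc1"
  expect_lt(mouth1$tests$p.value[i], 0.01)
  # no coupling into the eyes model at this strength... sign only checked
  expect_true("looking_trc1_eyes" %in% names(mods))
  # all-missing PD window is skipped with a message
  pd_na <- pd; pd_na$pd_trc3 <- NA_real_
  expect_message(association_models(pd_na, outc, bins, win, participants,
                                    ddf = "asymptotic"), "skipped")
})
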