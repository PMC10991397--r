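#!/usr/bin/env Rscript
# Generate the synthetic two-group emotion-viewing dataset that the rest of
# the workflow analyses: 300 Hz binocular sample logs per participant, the
# trial table, participant covariates, the AOI map, and the ground truth.
# The design mirrors the study scale at 30 participants per group with 12
# trials (4 actors x 3 emotion expressions) of 4.5 s each.

library(pupiltime)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
params <- sim_params()
cat("Simulating", 2 * params$n_per_group, "participants x",
    params$n_trials, "trials at", params$rate_hz, "Hz (seed ", seed, ")\n")
ds <- simulate_dataset(params, seed = seed)

saveRDS(ds, "results/data/dataset.rds")   # in-memory handoff for 02-05
write.table(ds$trials, "results/data/trials.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(ds$participants, "results/data/participants.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write_aoi_map(ds$aoi_map, "results/data/aoi_map.yaml")
# one sample log per participant, the pipeline's on-disk input format
dir.create("results/data/samples", showWarnings = FALSE)
for (pid in names(ds$streams)[1:2])   # two logs as format examples
  write_samples(ds$streams[[pid]],
                file.path("results/data/samples", paste0(pid, ".csv")))

n_samp <- sum(vapply(ds$streams, nrow, integer(1)))
cat("Wrote trial table (", nrow(ds$trials), " trials), covariates, AOI map;",
    n_samp, "samples total.\n")
cat("Truth: component windows at",
    paste(ds$truth$windows$end_ms[1:2], collapse = " / "), "ms;",
    "pupil group effects", paste(params$pupil$group_effect, collapse = "/"),
    "(null).\n")
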