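#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study cohort.
#
# The study's interview records are not deposited, so the analysis runs on a
# synthetic cohort calibrated to the published marginals: 43 patients,
# 24-h sleep median 690.5 min (78.6% above 660), ESS > 10 in 85%,
# MSLT < 8 min in 73.8%, published comorbidity frequencies, and stimulant
# exposure in the last five years for ~33/40 patients.

suppressPackageStartupMessages(library(ihsim))

seed <- 20
dir.create("results", showWarnings = FALSE)

records <- sample_cohort(config = generator_config(43, seed = seed))
write_patients(records, "results/cohort_records.yaml")

s <- cohort_summary(records)
calib <- data.frame(
  quantity = c("n patients", "median 24-h sleep (min)", "% sleep > 660 min",
               "% ESS > 10", "% MSLT < 8 min", "% depression"),
  calibrated = c(43, 690.5, 78.6, 85, 73.8, 27.3),
  synthetic = round(c(s$n, s$median_sleep_24h, s$pct_sleep_gt_660,
                      s$pct_ess_gt_10, s$pct_mslt_lt_8,
                      100 * s$prevalence[["depression_diagnosis"]]), 1))
write.csv(calib, "results/cohort_summary.csv", row.names = FALSE)

cat("Synthetic cohort written to results/cohort_records.yaml\n\n")
print(calib, row.names = FALSE)
cat("\nAt n = 43 the marginals scatter around the calibration targets;",
    "\nthe large-n recovery is exercised by the test suite.\n")
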