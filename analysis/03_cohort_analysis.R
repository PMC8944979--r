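#!/usr/bin/env Rscript
# Step 3 — simulate the study cohort and run the two-level statistics.
#
# A cohort of 49 female + 24 male subjects (two condyles each) is drawn
# from the generator whose defaults encode the study conditions, then
# summarized per pattern group (the study's Table-1 shape) and analyzed
# with the crude / adjusted / sex-stratified random-intercept battery (the
# Table-2 shape).

suppressPackageStartupMessages(library(condylometry))
dir.create("results", showWarnings = FALSE)

cohort <- simulate_cohort(cohort_spec(seed = 20260927))
report <- analyze_study(cohort)

write.csv(report$summaries, "results/cohort_group_summaries.csv",
          row.names = FALSE)
write.csv(report_table(report), "results/cohort_regressions.csv",
          row.names = FALSE)

print(report)

sexes <- tapply(cohort$volume_mm3, cohort$sex, mean)
message(sprintf(
  "Mean condylar volume: %.0f mm^3 in females, %.0f mm^3 in males (difference %.0f).",
  sexes["F"], sexes["M"], sexes["M"] - sexes["F"]))
for (v in c("divergence_deg", "gonial_deg")) {
  crude <- slope_of(report$continuous[[v]]$crude, v)
  message(sprintf(
    "Crude %s slope: %.1f mm^3/deg (95%% CI %.1f to %.1f, p = %.3g).",
    v, crude$estimate, crude$ci_lo, crude$ci_hi, crude$p_value))
}
message("The generator's negative vertical-pattern gradients are recovered; ",
        "single-cohort group-mean orderings wobble at this sample size ",
        "(see the methods vignette on sampling error vs. the ~60 mm^3 ",
        "divergence steps).")
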