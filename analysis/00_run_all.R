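#!/usr/bin/env Rscript
# Runs the whole analysis workflow in order. Each step is standalone; all
# outputs land under results/.
for (script in c("01_phantom_volumetry.R", "02_cephalometrics.R",
                 "03_cohort_analysis.R", "04_reliability_power.R",
                 "05_end_to_end_study.R")) {
  message("== ", script, " ==")
  source(file.path("analysis", script), echo = FALSE)
}
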