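#!/usr/bin/env Rscript
# Stage 3 — cohort analysis.
#
# Applies the exclusion cascade (flags, underweight, undersized strata),
# computes stratum mean profiles with SEMs per sex x BMI x age group,
# locates the age-independent intersection of the age-group profiles per
# sex x BMI group, and derives the scaling factor that converts a
# single-slice VAT area at that location into an estimated total volume.
# Also reports the sex comparisons (pooled t tests) and the Gaussian KDE
# of the femoral-head-to-L5 distances.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))),
                 "config.R"))
cfg <- study_config()

res <- analyze_cohort(cfg)
message("exclusions: ",
        paste(sprintf("%s=%d", res$excl$counts$criterion,
                      res$excl$counts$n_removed), collapse = ", "),
        "; retained n = ", nrow(res$excl$cohort))
message("factor table (reference location and scaling factor per sex x BMI group):")
for (i in seq_len(nrow(res$factors))) {
  message(sprintf("  %s %-3s  %-10s  factor %.0f",
                  res$factors$sex[i], res$factors$bmi_group[i],
                  res$factors$location[i], res$factors$factor[i]))
}
message("stratum statistics, factors (JSON + CSV), cohort summary, t tests ",
        "and distance KDE written under ", cfg$out_dir)
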