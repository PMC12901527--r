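#!/usr/bin/env Rscript
# Stage 4 — single-slice estimation and validation.
#
# Applies the sex- and BMI-specific factor table to every retained
# participant's slice area at the group's reference location, then
# validates the estimates against the volumetric reference: Pearson
# correlation and regression per sex x BMI group, mean signed error with
# sd per sex, the relative mean absolute error, and boxplot statistics of
# the errors per BMI x age group.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))),
                 "config.R"))
cfg <- study_config()

out <- estimate_stage(cfg)
message("validated ", nrow(out$estimates), " single-slice estimates")
for (i in seq_len(nrow(out$errors))) {
  e <- out$errors[i, ]
  message(sprintf("  %s: mean error %+.2f +- %.2f l, relative %.2f %%",
                  e$group, e$mean_error_l, e$sd_error_l, e$rmae_pct))
}
rng <- range(out$validation$r, na.rm = TRUE)
message(sprintf("  Pearson r across sex x BMI groups: %.2f-%.2f",
                rng[1], rng[2]))
message("estimates, validation summary and error boxplot statistics written ",
        "under ", cfg$out_dir)
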