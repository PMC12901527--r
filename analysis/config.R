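# Shared run configuration for the analysis drivers (sourced by 01-05).
# One seed governs every stage; outputs accumulate under results/run/.

suppressPackageStartupMessages(library(vatslice))

study_config <- function() {
  run_config(list(
    seed = 20250923L,
    n_participants = 11191L,
    masks_n = 3L,
    out_dir = "results/run",
    exclusions = list(fat_water_swap = 21L, corrupted = 2L,
                      missing_anthropometry = 27L, underweight = 84L,
                      small_stratum = 21L)
  ))
}
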