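# Shared setup for the analysis drivers: one configuration, one seed, one
# output directory. Every numbered script sources this file first, so the
# whole analysis is reproducible from a single place.

library(ntermflow)

CFG <- analysis_config(rng_seed = 101L)
PARAMS <- sim_params(seed = CFG$rng_seed)   # study-scale defaults:
                                            # 600 proteins, 1300 termini,
                                            # 3 genotypes x 4 replicates
RESULTS_DIR <- file.path("results")
DATA_DIR <- file.path(RESULTS_DIR, "simulated_data")
dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

save_tsv <- function(df, name) {
  write_results_tsv(df, file.path(RESULTS_DIR, name), seed = CFG$rng_seed)
  message("  wrote results/", name)
}
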