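#!/usr/bin/env Rscript
## Regenerates the small bundled fixture dataset and the golden pipeline
## outputs under inst/extdata/. Run from the repository root after any
## change to the generator or the pipeline output format:
##   Rscript scripts/make_fixtures.R

library(survenrich)

fixture_cfg <- function() {
  sim_config(
    n_samples = 40, n_genes = 120, seed = 101,
    nb_dispersion = 0.2,
    planted_sets = list(
      list(name = "planted_up", size = 12, beta = 1, log2fc = 1),
      list(name = "planted_down", size = 12, beta = -1, log2fc = -1)),
    censoring_fraction = 0.3,
    n_decoy_sets = 6, decoy_size = 12)
}

ext <- file.path("inst", "extdata")
write_simulated_dataset(fixture_cfg(), ext, mode = "survival")

golden <- file.path(ext, "golden")
run_pipeline(
  counts_path = file.path(ext, "counts.tsv"),
  gmt_path = file.path(ext, "sets.gmt"),
  survival_path = file.path(ext, "survival.tsv"),
  out_dir = golden,
  mode = "survival",
  min_size = 5L, n_perm = 500L, seed = 11L, quiet = TRUE)
unlink(file.path(golden, "manifest.json"))  # carries absolute paths
cat("fixtures written under", ext, "\n")
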