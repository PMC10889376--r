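#!/usr/bin/env Rscript
# Thin command-line wrapper over thermidr::run_pipeline(). Usage:
#   Rscript scripts/run_pipeline.R --seed 1 --out-dir results/run1

suppressMessages({
  library(optparse)
  library(thermidr)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out-dir", dest = "out_dir", type = "character",
              default = "pipeline_out"),
  make_option("--n-species", dest = "n_species", type = "integer",
              default = 32L),
  make_option("--min-species", dest = "min_species", type = "integer",
              default = 10L)
)))

res <- run_pipeline(opts$out_dir,
                    config = sim_config(seed = opts$seed,
                                        n_species = opts$n_species),
                    min_species = opts$min_species)
print(res$fits$contrast)
cat("outputs written to", opts$out_dir, "\n")
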