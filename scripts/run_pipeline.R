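#!/usr/bin/env Rscript
# Thin command-line wrapper around chromdiff::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R --outdir runs/demo [--seed 1]
#     [--config cfg.yaml] [--stages simulate,coverage,diffbind]

suppressPackageStartupMessages({
  library(optparse)
  library(chromdiff)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML file overriding simulation_config() defaults"),
  make_option("--outdir", type = "character", default = "chromdiff_run"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--stages", type = "character",
              default = "simulate,coverage,metagene,state_enrichment,cooccupancy,diffbind")
)))

cfg <- if (is.null(opts$config)) {
  simulation_config(seed = opts$seed)
} else {
  fields <- yaml::read_yaml(opts$config)
  fields$seed <- opts$seed
  do.call(simulation_config, fields)
}
stages <- strsplit(opts$stages, ",", fixed = TRUE)[[1]]
s <- run_pipeline(cfg, opts$outdir, stages = stages)
cat("run complete:", opts$outdir, "\n")
if (!is.null(s$diffbind))
  cat(sprintf("consensus regions: %d (sensitivity %.3f, FDR %.3f)\n",
              s$diffbind$n_consensus, s$diffbind$sensitivity,
              s$diffbind$fdr))
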