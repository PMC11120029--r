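#!/usr/bin/env Rscript

## Thin command-line wrapper over the package's pipeline functions.
##
##   Rscript scripts/pipeline.R demo   [--seed N] [--out DIR]
##   Rscript scripts/pipeline.R report --config FILE [--seed N] [--out DIR]
##
## `demo` runs the full synthetic pipeline at the default configuration;
## `report` does the same under a user YAML configuration. All stages
## (simulate, fit, select, melt, titrate, cleave-fit) are exported package
## functions and can be scripted directly for finer control.

suppressPackageStartupMessages({
  library(optparse)
  library(ClampKinetics)
})

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args)) args[[1L]] else "demo"
opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--out", type = "character", default = "pipeline-out")
)), args = args[-1L])

config <- if (is.null(opts$config)) defaultRunConfig() else readRunConfig(opts$config)
if (!is.null(opts$seed)) config$seed <- opts$seed

switch(cmd,
  demo = ,
  report = {
    runPipeline(config, outDir = opts$out)
  },
  stop("unknown subcommand: ", cmd, " (use 'demo' or 'report')")
)
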