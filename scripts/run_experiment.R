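#!/usr/bin/env Rscript

# Thin command-line wrapper over the package's scripted experiments:
#
#   Rscript scripts/run_experiment.R <scenario> [--config <file.json>]
#       [--seed <int>] [--out <dir>]
#
# Scenarios: tracking | drift | decoding | diffusion. The optional JSON
# config supplies extra arguments for the scenario's experiment_* function;
# --seed overrides the config's seed. Curves are written as tidy CSV with a
# JSON manifest in --out.

suppressPackageStartupMessages(library(gridlock))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("usage: run_experiment.R <scenario> [--config f] [--seed s] [--out d]")
}
scenario <- args[1]
cfg <- list()
out_dir <- NULL
i <- 2L
while (i <= length(args)) {
  if (args[i] == "--config") {
    cfg <- jsonlite::read_json(args[i + 1], simplifyVector = TRUE)
    i <- i + 2L
  } else if (args[i] == "--seed") {
    cfg$seed <- as.integer(args[i + 1]); i <- i + 2L
  } else if (args[i] == "--out") {
    out_dir <- args[i + 1]; i <- i + 2L
  } else {
    stop("unknown argument: ", args[i])
  }
}
cfg$scenario <- scenario
res <- run_experiment(cfg, out_dir = out_dir)
if (is.null(out_dir)) str(res, max.level = 1)
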