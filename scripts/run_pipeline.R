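#!/usr/bin/env Rscript

# Thin shell entry point over lriscape::run_pipeline(): simulate the
# default synthetic study and write the machine-readable run report.
#
#   Rscript scripts/run_pipeline.R --seed 17 --out report.json

suppressPackageStartupMessages(library(lriscape))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", "run_report.json")

report <- run_pipeline(run_config(seed = seed))
write_run_report(report, out)
cat("wrote", out, "\n")
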