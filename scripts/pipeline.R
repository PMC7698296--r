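#!/usr/bin/env Rscript
# Thin command-line wrapper over the farmvisits pipeline.
#
#   Rscript scripts/pipeline.R simulate --seed 1 --out out_dir
#       write a synthetic study (farms.csv, fixes.csv, landscape.geojson,
#       dem.asc, birds.csv, truth.json) to out_dir
#   Rscript scripts/pipeline.R run-all [--config cfg.yaml] --seed 1 --out out_dir
#       run the full workflow and write every artefact plus a manifest

suppressMessages(library(farmvisits))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: pipeline.R <simulate|run-all> [options]")
cmd <- args[1]
getopt <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(getopt("--seed", "1"))
out <- getopt("--out", "pipeline_out")
cfg_path <- getopt("--config", NA)

if (cmd == "simulate") {
  sim <- simulate_study(sim_config(seed = seed))
  paths <- write_study(sim, out)
  cat("wrote", length(paths), "files to", out, "\n")
} else if (cmd == "run-all") {
  cfg <- if (!is.na(cfg_path)) read_run_config(cfg_path) else run_config()
  cfg$out_dir <- out
  cfg$seed <- seed
  cfg$sim$seed <- seed
  res <- run_pipeline(cfg)
  cat("completed;", nrow(res$manifest), "artefacts in", out, "\n")
} else {
  stop("unknown subcommand: ", cmd)
}
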