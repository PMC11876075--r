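#!/usr/bin/env Rscript
# Thin command-line wrapper over the package pipeline.
#
#   Rscript scripts/ridgemotif.R simulate --seed 1 --out simdata/
#   Rscript scripts/ridgemotif.R run --seed 1 --out report/
#
# `simulate` writes the synthetic inputs (peak calls, motifs); `run`
# executes the full pipeline on a generated dataset and writes the stage
# TSVs plus manifest.json.

suppressPackageStartupMessages(library(ridgemotif))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L || !args[1L] %in% c("simulate", "run")) {
  stop("usage: ridgemotif.R <simulate|run> [--seed N] [--out DIR]")
}
cmd <- args[1L]
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", "ridgemotif_out")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- sim_config(seed = seed)

if (cmd == "simulate") {
  sim <- simulate_peak_calls(cfg)
  for (pop in names(sim$peaks)) {
    write_atlas(sim$peaks[[pop]],
                file.path(out, paste0(pop, ".narrowPeak")))
  }
  pwms <- random_pwms(cfg$n_groups, length = cfg$motif_length,
                      seed = seed)
  write_meme_pwms(pwms, file.path(out, "motifs.meme"))
  message("wrote simulated inputs to ", out)
} else {
  run_pipeline(cfg, out_dir = out)
  message("pipeline outputs in ", out)
}
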