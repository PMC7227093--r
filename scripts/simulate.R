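#!/usr/bin/env Rscript
# Run one scenario sweep and write iteration-level and aggregated CSV tables.
#
#   Rscript scripts/simulate.R --scenario 1 --reps 1000 --seed 1 \
#       --workers 1 --out results/scenario1 [--config my.dcf] [--plots]

suppressPackageStartupMessages({
  library(optparse)
  library(centersim)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--scenario", type = "integer", default = 1L),
  make_option("--reps", type = "integer", default = 1000L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--workers", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results"),
  make_option("--config", type = "character", default = NULL),
  make_option("--plots", action = "store_true", default = FALSE)
)))

cfg <- load_config(opts$config)
cfg$scenario <- opts$scenario
cfg$n_reps <- opts$reps
cfg$root_seed <- opts$seed
cfg$n_workers <- opts$workers

grid <- scenario_grid(opts$scenario)
message(sprintf("scenario %d: sweeping %s over %d values, %d reps each",
                grid$scenario, grid$varied, length(grid$values), opts$reps))
res <- run_scenario(grid, n_reps = opts$reps, root_seed = opts$seed,
                    n_workers = opts$workers, verbose = TRUE)

dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
write_results(res$iterations, file.path(opts$out, "iterations.csv"))
write_results(res$summary, file.path(opts$out, "summary.csv"))
write_results(res$supplementary, file.path(opts$out, "supplementary.csv"))
write_run_metadata(opts$out, cfg,
                   iteration_seeds(opts$seed, length(grid$values)))
if (opts$plots)
  for (s in c("fdr", "mspe", "sv", "cs"))
    plot_scenario(res, s, file.path(opts$out, sprintf("scenario%d_%s.png",
                                                      grid$scenario, s)),
                  log_x = opts$scenario == 2)
message("results written to ", opts$out)
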