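#!/usr/bin/env Rscript
# MSPE-estimator-quality experiment: approximated true prediction error of a
# signature versus its estimate from SC / MC validation cohorts.
#
#   Rscript scripts/estimator_quality.R --reps 1000 --val-sets 100 \
#       --approx-n 100000 --seed 1 --out results/estimator_quality

suppressPackageStartupMessages({
  library(optparse)
  library(centersim)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--reps", type = "integer", default = 1000L),
  make_option("--val-sets", type = "integer", default = 100L, dest = "val_sets"),
  make_option("--approx-n", type = "integer", default = 100000L, dest = "approx_n"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--workers", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/estimator_quality")
)))

q <- mspe_estimator_quality(hornung_params(beta_mean = 0.25),
                            n_iter = opts$reps, n_val_sets = opts$val_sets,
                            approx_n = opts$approx_n, root_seed = opts$seed,
                            n_workers = opts$workers)
dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
write_results(q$summary, file.path(opts$out, "estimator_quality_summary.csv"))
write_results(q$iterations, file.path(opts$out, "estimator_quality_iterations.csv"))
print(q$summary, digits = 3)
message("results written to ", opts$out)
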