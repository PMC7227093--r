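#!/usr/bin/env Rscript
# Re-aggregate iteration-level results written by simulate.R.
#
#   Rscript scripts/summarize.R --in results/scenario1 --out results/scenario1

suppressPackageStartupMessages({
  library(optparse)
  library(centersim)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--in", type = "character", default = "results", dest = "indir"),
  make_option("--out", type = "character", default = NULL)
)))
outdir <- if (is.null(opts$out)) opts$indir else opts$out

iters <- read_results(file.path(opts$indir, "iterations.csv"),
                      required_cols = c("disc_design", "val_design", "fdr",
                                        "mspe", "sv", "cs", "sig_length",
                                        "nonempty"))
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
write_results(aggregate_scores(iters), file.path(outdir, "summary.csv"))
write_results(supplementary_summaries(iters),
              file.path(outdir, "supplementary.csv"))
message("summaries written to ", outdir)
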