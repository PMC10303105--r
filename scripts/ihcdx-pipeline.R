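#!/usr/bin/env Rscript

# Thin command-line wrapper over ihcdx::run_pipeline(): simulate (or
# read) a cohort, score it, evaluate the diagnostic marker panel,
# compare clinical covariates, and run the survival analyses, writing
# the TSV/JSON report bundle to --out-dir.

suppressMessages({
  library(optparse)
  library(ihcdx)
})

parser <- OptionParser(
  usage = "Rscript scripts/ihcdx-pipeline.R [options]",
  option_list = list(
    make_option("--input", type = "character", default = NULL,
                help = "cohort CSV/TSV; omitted = simulate the default cohort"),
    make_option("--percent", action = "store_true", default = FALSE,
                help = "input fractions are 0-100 percentages"),
    make_option("--seed", type = "integer", default = 1,
                help = "simulation seed [default %default]"),
    make_option("--out-dir", type = "character", default = "ihcdx_report",
                dest = "out_dir", help = "output directory"),
    make_option("--cutoff-y705", type = "double", default = NA,
                dest = "cut_y", help = "fixed Y705 cutoff (default: Youden)"),
    make_option("--cutoff-s727", type = "double", default = NA,
                dest = "cut_s", help = "fixed S727 cutoff (default: Youden)")
  )
)
opt <- parse_args(parser)

cutoffs <- c(y705 = opt$cut_y, s727 = opt$cut_s)
cutoffs <- cutoffs[!is.na(cutoffs)]
if (length(cutoffs) == 0) cutoffs <- NULL

res <- run_pipeline(pipeline_config(
  input = opt$input, percent = opt$percent, seed = opt$seed,
  out_dir = opt$out_dir, cutoffs = cutoffs
))
message("report bundle written to ", res$out_dir)
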