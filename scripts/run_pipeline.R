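#!/usr/bin/env Rscript

# Thin command-line wrapper over qsarmix::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R --config config.yaml [--seed 1]
#                                  [--outdir results]

suppressMessages({
  library(optparse)
  library(qsarmix)
})

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character",
              help = "YAML pipeline configuration [required]"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the config's master seed"),
  make_option("--outdir", type = "character", default = NULL,
              help = "override the config's output directory")
))
opt <- parse_args(parser)
if (is.null(opt$config)) {
  print_help(parser)
  quit(status = 2)
}

res <- run_pipeline(opt$config, seed = opt$seed, outdir = opt$outdir)
print(res$report)
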