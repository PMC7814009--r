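#!/usr/bin/env Rscript
# Thin command-line wrapper over clonalpop::run_pipeline().
#
# Usage:
#   Rscript scripts/clonalpop.R <stage> [--config cfg.yaml] [--seed N]
#                               [--out DIR] [--force] [--verbose]
# where <stage> is one of: simulate, variants, structure, vaf, census,
# growth, all.

suppressMessages({
  library(optparse)
  library(clonalpop)
})

parser <- OptionParser(
  usage = "%prog <stage> [options]",
  option_list = list(
    make_option("--config", type = "character", default = NULL,
                help = "YAML/JSON run configuration (defaults used if absent)"),
    make_option("--seed", type = "integer", default = NULL,
                help = "override the configuration seed"),
    make_option("--out", type = "character", default = NULL,
                help = "override the output directory"),
    make_option("--force", action = "store_true", default = FALSE,
                help = "overwrite existing outputs"),
    make_option("--verbose", action = "store_true", default = FALSE)
  ))
parsed <- parse_args(parser, positional_arguments = 1L)
stage <- parsed$args
opts <- parsed$options

all_stages <- c("simulate", "variants", "structure", "vaf", "census",
                "growth")
if (!stage %in% c(all_stages, "all")) {
  stop("unknown stage '", stage, "'; choose one of: ",
       paste(c(all_stages, "all"), collapse = ", "))
}

cfg <- if (is.null(opts$config)) default_run_config() else {
  if (!file.exists(opts$config)) {
    message("missing input file: ", opts$config)
    quit(status = 2L)
  }
  read_run_config(opts$config)
}
if (!is.null(opts$seed)) cfg$seed <- opts$seed
if (!is.null(opts$out)) cfg$out_dir <- opts$out
cfg$force <- opts$force

stages <- if (stage == "all") all_stages else
  all_stages[seq_len(match(stage, all_stages))]
if (opts$verbose) {
  message("running stages: ", paste(stages, collapse = " -> "),
          " (seed ", cfg$seed, ", out ", cfg$out_dir, ")")
}

status <- tryCatch({
  run_pipeline(cfg, stages = stages)
  0L
}, error = function(e) {
  message("pipeline failed: ", conditionMessage(e))
  marker <- file.path(cfg$out_dir, "run_report.json.failed")
  try(writeLines(conditionMessage(e), marker), silent = TRUE)
  1L
})
quit(status = status)
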