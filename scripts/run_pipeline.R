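#!/usr/bin/env Rscript
# Thin command-line wrapper over tdnarch::run_pipeline().
#   Rscript scripts/run_pipeline.R --config config.yaml [--seed N] [--out DIR]
# Exit codes: 0 ok, 2 configuration error, 3 input error.

suppressMessages(library(tdnarch))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(config = NULL, seed = NULL, out = "tdnarch_out")
i <- 1
while (i <= length(args)) {
  key <- args[i]
  if (key %in% c("--config", "--seed", "--out")) {
    val <- args[i + 1]; i <- i + 2
    opt[[sub("^--", "", key)]] <- val
  } else {
    message("unknown argument: ", key); quit(status = 2)
  }
}
if (is.null(opt$config)) {
  message("usage: Rscript scripts/run_pipeline.R --config FILE [--seed N] [--out DIR]")
  quit(status = 2)
}

cfg <- tryCatch(pipeline_config(opt$config), error = function(e) {
  message("configuration error: ", conditionMessage(e)); quit(status = 2)
})
if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)

report <- tryCatch(run_pipeline(cfg), error = function(e) {
  message("pipeline error: ", conditionMessage(e)); quit(status = 3)
})
paths <- write_report(report, opt$out)
print(report)
message("wrote: ", paste(paths, collapse = ", "))
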