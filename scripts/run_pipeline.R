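#!/usr/bin/env Rscript
# Run the full synthetic-trial safety analysis and write its result bundle.
# Usage: Rscript scripts/run_pipeline.R --seed 1 --out results/run1
#
# Any default_config() entry can be overridden with --set key=value (numeric
# values only), e.g. --set margin_hr=4 --set bonferroni_cardiac=6.

suppressMessages({
  library(optparse)
  library(hrvtrial)
})

parser <- OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/run"),
  make_option("--set", type = "character", action = "append", default = NULL)
))
opts <- parse_args(parser)

cfg <- default_config(seed = opts$seed)
for (kv in opts$set) {
  parts <- strsplit(kv, "=", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !parts[1L] %in% names(cfg)) {
    stop("bad --set entry: ", kv)
  }
  cfg[[parts[1L]]] <- as.numeric(parts[2L])
}

res <- run_pipeline(cfg, out_dir = opts$out)
cat(res$log, sep = "\n")
cat("results written to", opts$out, "\n")
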