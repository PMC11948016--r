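#!/usr/bin/env Rscript
# Thin command-line wrapper over the package's pipeline runners:
#   Rscript scripts/lipoclust.R generate --config cfg.json [--seed S] [--out DIR]
#   Rscript scripts/lipoclust.R quantify --config cfg.json [--out DIR]
#   Rscript scripts/lipoclust.R fit      --config cfg.json [--out DIR]
# Flags override the corresponding config fields.

suppressPackageStartupMessages({
  library(optparse)
  library(lipoclust)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L || !args[1] %in% c("generate", "quantify", "fit")) {
  stop("usage: lipoclust.R <generate|quantify|fit> --config <json> [--seed S] [--out DIR]")
}
command <- args[1]

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", help = "JSON config file"),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--out", type = "character", default = NULL)
))
opts <- parse_args(parser, args = args[-1])
if (is.null(opts$config)) stop("--config is required")

config <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
if (!is.null(opts$seed)) config$seed <- opts$seed
if (!is.null(opts$out)) config$out <- opts$out

switch(command,
       generate = run_generate(config),
       quantify = run_quantify(config),
       fit = run_fit(config))
invisible(NULL)
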