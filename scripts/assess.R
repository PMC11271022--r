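#!/usr/bin/env Rscript
# Run the full assessment pipeline from a YAML configuration and write the
# report bundle (JSON report, text summary, geospatial layers).
#
# Usage: Rscript scripts/assess.R --config cfg.yaml [--seed 1] [--out report_dir]

suppressPackageStartupMessages({
  library(optparse)
  library(kbascope)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML configuration file (see ?run_assessment)"),
  make_option("--seed", type = "integer", default = 1L,
              help = "seed overriding the configuration [default %default]"),
  make_option("--out", type = "character", default = "assessment_report",
              help = "output directory [default %default]")
)))

cfg <- if (is.null(opts$config)) list() else yaml::read_yaml(opts$config)
cfg$seed <- opts$seed

report <- run_assessment(cfg)
print(report)
write_report(report, opts$out)
cat("report written to", opts$out, "\n")
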