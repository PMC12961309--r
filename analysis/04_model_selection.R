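#!/usr/bin/env Rscript
# Regress the mean relative GMFA of each sweep on the parameter value
# with linear, quadratic and exponential models; select by minimum SSE
# and report r = sqrt(1 - SSE/SST) and the model's test p-value.
# Reads the CSVs written by analysis/03_sweep_inhibition.R.
#
# Usage: Rscript analysis/04_model_selection.R [--parameters b,C4]

suppressPackageStartupMessages({
  library(optparse)
  library(vtep)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--parameters", default = "b,C4"))))

report <- list()
for (par in strsplit(opts$parameters, ",")[[1]]) {
  path <- sprintf("results/sweep_%s.csv", par)
  if (!file.exists(path))
    stop("missing ", path, "; run analysis/03_sweep_inhibition.R first")
  rec <- read.csv(path)
  overall <- rec[rec$window == "overall", ]
  subj <- aggregate(gmfa_rel ~ percent + value + subject,
                    data = overall, FUN = mean)
  m <- aggregate(gmfa_rel ~ percent + value, data = subj, FUN = mean)
  fits <- fit_models(m$value, m$gmfa_rel)
  cat("=== parameter", par, "===\n")
  print(regression_table(fits), digits = 4)
  cat("selected:", fits$selected, "\n\n")
  report[[par]] <- regression_table(fits)
}
jsonlite::write_json(report, "results/regression_report.json",
                     auto_unbox = TRUE, digits = NA,
                     dataframe = "rows", pretty = TRUE)
cat("report -> results/regression_report.json\n")
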