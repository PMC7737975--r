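#!/usr/bin/env Rscript
# Clinical metrics per session: EDV, ESV, LVEF and the four peak
# circumferential strains, from the per-slice measurement table.

suppressPackageStartupMessages({
  library(cmragree)
  library(dplyr)
})

out_dir <- "results"
measurements <- readr::read_csv(file.path(out_dir, "measurements.csv"),
                                show_col_types = FALSE) |>
  filter(type %in% c("manual", "automated"))
config <- read_phantom_config(file.path(out_dir, "phantom_config.yaml"))

metrics <- study_metrics(measurements, slice_spacing = config$slice_spacing)
stopifnot(nrow(metrics) == length(unique(measurements$session_id)),
          !anyNA(metrics))
message(sprintf("computed metrics for %d sessions", nrow(metrics)))

truth <- readr::read_csv(file.path(out_dir, "truth_metrics.csv"),
                         show_col_types = FALSE)
auto <- metrics |> filter(type == "automated")
message(sprintf("automated-session GCS %.2f%% vs analytic truth %.2f%%",
                auto$GCS, truth$GCS))

readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
message("wrote ", file.path(out_dir, "metrics.csv"))
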