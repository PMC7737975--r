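#!/usr/bin/env Rscript
# Agreement analysis: group summary table, paired intra-/inter-software
# comparisons with the Bonferroni-corrected flag, Bland-Altman contour-length
# agreement (with the automated single run duplicated across repetitions),
# and the accompanying figures.

suppressPackageStartupMessages({
  library(cmragree)
  library(dplyr)
})

out_dir <- "results"
fig_dir <- file.path(out_dir, "figures")
dir.create(fig_dir, showWarnings = FALSE, recursive = TRUE)

alpha <- 0.05
measurements <- readr::read_csv(file.path(out_dir, "measurements.csv"),
                                show_col_types = FALSE) |>
  filter(type %in% c("manual", "automated"))
metrics <- readr::read_csv(file.path(out_dir, "metrics.csv"),
                           show_col_types = FALSE)

table1 <- build_table1(metrics)
table2 <- build_table2(metrics, alpha = alpha)
readr::write_csv(table1, file.path(out_dir, "table1.csv"))
readr::write_csv(table2, file.path(out_dir, "table2.csv"))
message(sprintf("summary rows: %d; paired comparisons: %d (threshold p <= %.3f)",
                nrow(table1), nrow(table2), unique(table2$p_threshold)))
sig <- table2 |> filter(significant)
message("flagged comparisons: ",
        if (nrow(sig)) paste(sig$comparison, sig$metric, collapse = "; ")
        else "none")

ba <- bland_altman_study(measurements)
readr::write_csv(ba, file.path(out_dir, "bland_altman.csv"))
for (row in which(ba$repetition == "pooled")) {
  message(sprintf("%-18s bias %+.2f cm, LoA [%.2f, %.2f]",
                  ba$comparison[row], ba$bias[row],
                  ba$loa_low[row], ba$loa_high[row]))
}

# figures: Bland-Altman scatter for the manual-manual pairing, metric boxplots
manual <- measurements |> filter(type == "manual")
os <- manual |> filter(software == "OsiriX") |> arrange(reader, repetition, slice, frame)
sc <- manual |> filter(software == "ScanIP") |> arrange(reader, repetition, slice, frame)
ba_pair <- bland_altman(os$perimeter_cm, sc$perimeter_cm)
ggplot2::ggsave(file.path(fig_dir, "bland_altman_scanip_vs_osirix.png"),
                plot_bland_altman(ba_pair, "ScanIP vs OsiriX contour lengths"),
                width = 6, height = 4, dpi = 150)
ggplot2::ggsave(file.path(fig_dir, "metric_boxplots.png"),
                plot_metric_boxplots(metrics), width = 9, height = 6, dpi = 150)

log_lines <- c(sprintf("cmragree %s", utils::packageVersion("cmragree")),
               sprintf("alpha = %.3f, bonferroni m = %d, threshold = %.5f",
                       alpha, 7L, bonferroni_threshold(alpha, 7)),
               sprintf("sessions: %d", length(unique(metrics$session_id))),
               sprintf("run at %s", format(Sys.time(), tz = "UTC")))
writeLines(log_lines, file.path(out_dir, "run_log.txt"))
message("agreement outputs written under ", out_dir)
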