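#!/usr/bin/env Rscript
# Simulate the multi-reader multi-software LV contouring study.
#
# Generates the default phantom study — 7 readers x 2 manual software packages
# x 2 repetitions (28 sessions) plus one automated session — and writes every
# session's contours as JSON, the analytic ground truth as CSV, the automated
# session's mask stack as NIfTI, and a manifest recording seed and config.

suppressPackageStartupMessages(library(cmragree))

seed <- 1215
out_dir <- "results"
sess_dir <- file.path(out_dir, "sessions")
dir.create(sess_dir, recursive = TRUE, showWarnings = FALSE)

config <- phantom_config(seed = seed)
print(config)

study <- generate_study(config)
message(sprintf("generated %d sessions (%d manual + 1 automated)",
                length(study$sessions), length(study$sessions) - 1))

for (sess in study$sessions) {
  write_contours_json(sess, file.path(sess_dir, paste0(sess$session_id, ".json")))
}

write_truth_csv(study$truth, file.path(out_dir, "truth.csv"))
write_phantom_config(config, file.path(out_dir, "phantom_config.yaml"))

# masks for the automated session only: the hull measurement chain reads these
auto <- study$sessions[[paste0(config$automated_label, "_auto")]]
masks <- array(0L, dim = c(config$grid_size, config$grid_size,
                           config$n_slices, config$n_frames))
for (i in seq_len(nrow(auto$contours))) {
  masks[, , auto$contours$slice[i], auto$contours$frame[i]] <-
    rasterize_mask(auto$contours$points[[i]], config)
}
write_mask_nifti(masks, file.path(out_dir, "CVI42_auto_masks.nii.gz"),
                 config$pixel_spacing, config$slice_spacing)

manifest <- list(seed = seed,
                 package_version = as.character(utils::packageVersion("cmragree")),
                 config_hash = rlang::hash(config),
                 n_sessions = length(study$sessions),
                 created = format(Sys.time(), tz = "UTC"))
jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE)
message("simulation written under ", out_dir)
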