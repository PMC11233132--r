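#!/usr/bin/env Rscript
# Generate the reference synthetic dataset and write it out as plain-text
# activity tables, the true connectivity weights, the ROI mask, and the
# condition design. Everything downstream (02-05) can be reproduced from
# these files or regenerated directly from the same config.

suppressMessages(library(cbrecruit))

out_dir <- "results/dataset"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 7L, gating_gain = 0.5)
ds <- simulate_dataset(cfg)

cat("Reference dataset:", cfg$n_subjects, "subjects,",
    cfg$n_conditions_train, "training +", cfg$n_conditions_test,
    "test conditions,", cfg$n_parcels, "parcels ->", cfg$n_voxels,
    "voxels; gating gain", cfg$gating_gain, "on",
    paste(cfg$gated_conditions, collapse = ", "), "\n")

for (s in names(ds$cortex_train)) {
  write_activity_table(ds$cortex_train[[s]],
                       file.path(out_dir, paste0(s, "_cortex_train.tsv")))
  write_activity_table(ds$cerebellum_train[[s]],
                       file.path(out_dir, paste0(s, "_cerebellum_train.tsv")))
  write_activity_table(ds$cortex_test[[s]],
                       file.path(out_dir, paste0(s, "_cortex_test.tsv")))
  write_activity_table(ds$cerebellum_test[[s]],
                       file.path(out_dir, paste0(s, "_cerebellum_test.tsv")))
}
write_connectivity_model(ds$true_model, file.path(out_dir, "w_true.tsv"))
write_roi_mask(ds$roi, file.path(out_dir, "roi.txt"))
write_condition_design(ds$design, file.path(out_dir, "design.json"))
jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("wrote", length(list.files(out_dir)), "files to", out_dir, "\n")
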