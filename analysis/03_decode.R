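#!/usr/bin/env Rscript
# Stage 3: decode every subject x ROI pattern set.
#
# Leave-one-trial-out cross-validation; in each fold the most informative
# radius-3 searchlight is selected by nested leave-one-trial-out scoring on
# the training trials only, a linear SVM (C = 1) is trained per ECOC
# dichotomy, and the held-out trial is predicted by Hamming decoding.

library(mtlmvpa)

cfg <- load_config("results/experiment_config.json")
dir.create("scratch/decoded", recursive = TRUE, showWarnings = FALSE)

roi_ids <- c("HC_L", "HC_R", "EPC_L", "EPC_R", "PHC_L", "PHC_R")
rows <- list()
for (s in seq_len(cfg$n_subjects)) {
  scfg <- subject_synth_config(cfg, s)
  for (id in roi_ids) {
    ps <- read_pattern_set(file.path("scratch/patterns",
                                     sprintf("subj-%02d_%s", s, id)))
    res <- loto_crossval(ps, c_param = cfg$c_param,
                         radius_voxels = cfg$radius_voxels,
                         score_mode = cfg$score_mode)
    write_decoding_result(res, file.path("scratch/decoded",
                                         sprintf("subj-%02d_%s", s, id)),
                          subject = s)
    vol <- ncol(ps$X) * scfg$voxel_size_mm^3
    rows[[length(rows) + 1]] <-
      data.frame(subject = s, region = res$roi_label,
                 hemisphere = res$hemisphere, n_trials = res$n_folds,
                 accuracy = res$accuracy, roi_volume_mm3 = vol)
  }
  message(sprintf("subject %02d decoded: %s", s,
                  paste(sprintf("%s %.0f%%", roi_ids,
                                100 * vapply(rows[(length(rows) - 5):length(rows)],
                                             function(r) r$accuracy,
                                             numeric(1))), collapse = ", ")))
}

acc <- do.call(rbind, rows)
write.csv(acc, "results/accuracies.csv", row.names = FALSE)
message(sprintf("wrote results/accuracies.csv (%d rows)", nrow(acc)))
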