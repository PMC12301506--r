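#!/usr/bin/env Rscript
# Predicted hemodynamic responses: per-stimulus MEG feature values are
# placed as impulses at the stimulus onsets and convolved with the
# canonical HRF (time-to-peak shortened by 0.5 s for total hemoglobin).
# Writes the Method-1 AUCs and Method-2 sample values per feature and
# frequency for the subject simulated in step 02.

library(megdot)
dir.create("results", showWarnings = FALSE)

features <- read.csv("results/meg_features_subject1.csv")
trains <- lapply(stats::setNames(nm = c(0.5, 1, 2, 4)), make_stimulus_train)
pred <- predict_subject_responses(features, trains)
write.csv(pred, "results/predicted_responses_subject1.csv",
          row.names = FALSE)

auc <- reshape(pred[, c("subject", "frequency", "feature_id", "auc_pred")],
               idvar = "frequency", timevar = "feature_id",
               direction = "wide", drop = "subject")
message("Method-1 predicted AUCs (1-9 s window) per frequency:")
print(auc, digits = 3)
message("each subject contributes 4 frequencies x 5 time samples = 20 ",
        "Method-2 samples per feature")
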