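#!/usr/bin/env Rscript
# Calibration of the minimum cluster volume against a null ensemble:
# with the neurovascular coupling switched off, how often does smoothed
# reconstruction noise alone produce an L3 (voxel p < 0.01) cluster?
# The rule is calibrated on 100 null datasets and its family-wise
# false-positive rate evaluated on 200 independent ones.

library(megdot)
dir.create("results", showWarnings = FALSE)

config <- pipeline_config(n_subjects = 3, n_repetitions = 3,
                          n_sources = 8, n_detectors = 8,
                          coupling = NULL, seed = 99)
ctx <- pipeline_context(config)
design <- meg_design(config, ctx)

cal_seeds <- vapply(1:100, function(i) child_seed(99, 2000 + i), integer(1))
cal <- null_max_cluster_volumes(config, cal_seeds, ctx = ctx,
                                design = design)
rule <- calibrate_min_volume(cal, target_fpr = 0.05,
                             voxel_volume = config$voxel_size^3)
message("calibrated minimum cluster volume: ", rule$min_volume,
        " mm^3 (null L3 clusters reach ",
        stats::quantile(cal, 0.95), " mm^3 at the 95th percentile)")

eval_seeds <- vapply(1:200, function(i) child_seed(99, 4000 + i), integer(1))
ev <- null_max_cluster_volumes(config, eval_seeds, ctx = ctx,
                               design = design)
fpr <- mean(ev >= rule$min_volume)
message(sprintf("family-wise false-positive rate on 200 fresh null datasets: %.3f", fpr))
write.csv(data.frame(min_volume = rule$min_volume,
                     calibration_fpr = rule$fpr_estimate,
                     evaluation_fpr = fpr),
          "results/null_calibration.csv", row.names = FALSE)
message("note: the spatially smoothed reconstruction noise of this sparse ",
        "desk-scale probe produces much larger null clusters than a ",
        "voxelwise-independent null would, which is why the rule must be ",
        "calibrated rather than fixed a priori")
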