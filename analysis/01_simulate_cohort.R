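#!/usr/bin/env Rscript
# Stage 1: simulate the study's raw inputs.
#
# One cohort of 22 observers runs an orientation-identification session
# (pre block + 5 training blocks, 100 trials each), generated from the
# DR-TH-Ter diffusion model with rising drift rate, falling threshold
# and falling nondecision time. EV glutamate is coupled to each
# subject's true drift-rate change (target r = -0.5); ROI time series
# are generated separately at stage 3. Tables land in scratch/data/.

library(driftlearn)

dir.create("scratch/data", recursive = TRUE, showWarnings = FALSE)
cfg <- cohort_config(seed = 20260926 %% 100000)

coh <- gen_behavior_cohort(cfg)
write_behavior(coh$trials, "scratch/data/behavior.csv")
write.table(coh$truth, "scratch/data/behavior_truth.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

mrs <- gen_mrs_table(cfg, coh$truth$delta_dr_true,
                     subjects = coh$truth$subject)
write_mrs_table(mrs, "scratch/data/mrs.tsv")

cat("subjects:", length(unique(coh$trials$subject)),
    "| trials:", nrow(coh$trials),
    "| mean pre accuracy:",
    round(mean(coh$trials$correct[coh$trials$block == "pre"]), 3), "\n")
cat("true delta-DR: mean", round(mean(coh$truth$delta_dr_true), 3),
    "sd", round(sd(coh$truth$delta_dr_true), 3), "\n")
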