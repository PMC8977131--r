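#!/usr/bin/env Rscript
# Stage 5: the stimulation experiment. Two arms train on the same task;
# the sham arm keeps the learning trajectory while anodal stimulation
# suppresses the drift-rate gain. A mixed Group (anodal, sham) x Block
# (pre, max-training) ANOVA tests whether stimulation blunts learning.

library(driftlearn)

cfg <- cohort_config(seed = (20260926 + 7) %% 100000)
res <- run_pipeline(pipeline_config("tdcs", cohort = cfg))

write.table(res$accuracy, "results/tdcs_accuracy.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(res$anova_accuracy, "results/tdcs_anova.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

print(res$anova_accuracy)
for (g in c("anodal", "sham")) {
  a <- res$accuracy[res$accuracy$group == g, ]
  ph <- paired_t(a$post, a$pre)
  cat("post hoc", g, ": t(", ph$df, ") =", round(ph$t, 2),
      ", p =", round(ph$p, 4), "(gate at 0.025, Bonferroni for 2 tests)\n")
}
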