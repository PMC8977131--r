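#!/usr/bin/env Rscript
# Stage 2: screen observers, fit the five block-constrained diffusion
# models per subject, select the family member by mean BIC, and compute
# the pre-to-max-training learning deltas under the selected model.

library(driftlearn)

trials <- read_behavior("scratch/data/behavior.csv")
subjects <- unique(trials$subject)
seed <- 20260926 %% 100000

screen <- data.frame(subject = subjects, included = vapply(subjects,
  function(s) screen_subject(trials[trials$subject == s, ])$include,
  logical(1)))
write.table(screen, "results/screening.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
kept <- screen$subject[screen$included]
cat("screened out", sum(!screen$included), "of", length(subjects),
    "subjects\n")

ctrl <- fit_control(multistart = 1, quad = c(3, 3, 4))
fits <- lapply(kept, function(s)
  fit_all_models(trials[trials$subject == s, ], control = ctrl, seed = seed))
names(fits) <- kept

sel <- select_model(fits)
cat("selected model:", sel$model, "\n")
print(round(sel$mean_bic, 2))
write.table(data.frame(model = names(sel$mean_bic),
                       mean_bic = round(sel$mean_bic, 2),
                       selected = names(sel$mean_bic) == sel$model),
            "results/mean_bic.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

deltas <- do.call(rbind, lapply(kept, function(s) {
  f <- fits[[s]][[sel$model]]
  if (!isTRUE(f$converged)) return(NULL)
  cbind(subject = s, learning_deltas(f, block_summaries(
    trials[trials$subject == s, ])))
}))
write.table(deltas, "results/deltas.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

cat("paired t (accuracy, max vs pre): t =",
    round(paired_t(deltas$d_accuracy, rep(0, nrow(deltas)))$t, 2), "\n")
cat("mean delta-DR:", round(mean(deltas$d_DR), 3),
    "| mean delta-TH:", round(mean(deltas$d_TH), 3),
    "| mean delta-Ter:", round(mean(deltas$d_Ter), 3), "\n")
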