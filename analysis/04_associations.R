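#!/usr/bin/env Rscript
# Stage 4: the association battery. MRS concentrations are quality
# filtered and CSF corrected; robust two-predictor regressions relate
# each brain measure (EV/DLPFC Glu and GABA+, EV-DLPFC connectivity) to
# the drift-rate and threshold changes, with standardized effect sizes
# r = sign(t) * sqrt(t^2 / (t^2 + df)); the Glu-vs-DR and Glu-vs-TH
# relationships are compared as dependent correlations (Steiger Z1*).

library(driftlearn)

deltas <- read.delim("results/deltas.tsv")
conn <- read.delim("results/connectivity.tsv")
mrs <- mrs_prepare(read_mrs_table("scratch/data/mrs.tsv"))
cat("MRS rows excluded by QC:", nrow(mrs$log), "\n")

wide <- function(region, metab) {
  m <- mrs$measures
  sel <- m$region == region & m$metabolite == metab
  setNames(m$conc[sel], m$subject[sel])
}
tab <- data.frame(
  subject = deltas$subject,
  d_dr = deltas$d_DR, d_th = deltas$d_TH,
  ev_glu = unname(wide("EV", "Glu")[deltas$subject]),
  ev_gaba = unname(wide("EV", "GABA+")[deltas$subject]),
  dlpfc_glu = unname(wide("DLPFC", "Glu")[deltas$subject]),
  dlpfc_gaba = unname(wide("DLPFC", "GABA+")[deltas$subject]),
  conn_z = conn$mean_z[conn$pair == "EV-DLPFC"][
    match(deltas$subject, conn$subject[conn$pair == "EV-DLPFC"])])
tab <- tab[complete.cases(tab), ]

bat <- association_battery(tab, c("ev_glu", "ev_gaba", "dlpfc_glu",
                                  "dlpfc_gaba", "conn_z"))
bat2 <- association_battery(tab, "conn_z", c("ev_glu", "ev_gaba"))
out <- rbind(bat, bat2)
write.table(out, "results/associations.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
show <- out$outcome %in% c("ev_glu", "conn_z") | out$significant
print(out[show, c("outcome", "predictor", "b", "t", "df", "r", "p")],
      digits = 3)

st <- compare_dependent_corrs(cor(tab$ev_glu, tab$d_dr),
                              cor(tab$ev_glu, tab$d_th),
                              cor(tab$d_dr, tab$d_th), nrow(tab))
cat("EV Glu: DR-change vs TH-change relationship (", st$method, "): z =",
    round(st$z, 2), ", p =", round(st$p, 3), "\n")
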