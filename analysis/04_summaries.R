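#!/usr/bin/env Rscript
# Summarize the cohort: per-plan mean +/- SD for every metric with one-way
# ANOVA across plan types (Tables 2-4 style), plus DVH curves for a
# representative phantom.

library(bnctplan)

metrics <- read.csv("results/cohort_metrics.csv")
summ <- summarize_cohort(metrics)
write.csv(summ, "results/cohort_summary.csv", row.names = FALSE)

show <- function(col, label, digits = 2) {
  s <- summ[summ$metric == col, ]
  cat(sprintf("  %-22s %s   ANOVA p = %s\n", label,
              paste(sprintf(paste0("%.", digits, "f +/- %.", digits, "f (%s)"),
                            s$mean, s$sd, s$plan), collapse = "  "),
              format.pval(s$anova_p[1], digits = 3)))
}
cat("Cohort summary (12 phantoms):\n")
show("CTV_min", "CTV min (Gy-Eq)")
show("CTV_D95", "CTV D95 (Gy-Eq)")
show("HI", "homogeneity index")
show("gain", "gain CTVmin/NTmax")
show("NB_Dmax", "normal brain Dmax")
show("NB_Dmean", "normal brain Dmean")
show("L_ON_Dmax", "left optic nerve Dmax")
show("CW_Dmax", "circle of Willis Dmax")
show("total_minutes", "beam-on time (min)", 1)

# pairwise comparisons for the headline metrics
for (col in c("gain", "NB_Dmax")) {
  groups <- split(metrics[[col]], metrics$plan)
  a <- one_way_anova(groups)
  cat(sprintf("\n%s pairwise (Tukey):\n", col))
  print(a$pairwise, row.names = FALSE, digits = 3)
}

# organ-at-risk tolerance verdicts
cat("\nOAR tolerance pass rates:\n")
for (col in grep("_pass$", names(metrics), value = TRUE))
  for (p in unique(metrics$plan))
    cat(sprintf("  %-10s %s: %d/%d\n", col, p,
                sum(metrics[[col]][metrics$plan == p]),
                sum(metrics$plan == p)))

# DVH curves for one representative phantom, 4F plan
ph <- generate_head_phantom(phantom_params(seed = 101))
plan <- plan_treatment(ph, standard_field_set(4))
st <- ph$structures
dvhs <- lapply(c("CTV", "NB", "L_ON", "R_ON", "CW"), function(nm) {
  dvh <- cumulative_dvh(plan$dose, st$masks[[nm]], st$geom)
  data.frame(structure = nm, dose_GyEq = dvh$dose,
             volume_fraction = dvh$volume_fraction)
})
write.csv(do.call(rbind, dvhs), "results/dvh_phantom01_4F.csv",
          row.names = FALSE)
cat("\nWrote results/cohort_summary.csv and results/dvh_phantom01_4F.csv\n")
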