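#!/usr/bin/env Rscript
# Cumulative incidence of the case event with death as a competing risk
# (Aalen-Johansen on the age scale with delayed entry), by sex.

library(twinliab)

dir.create("results", showWarnings = FALSE)
dir.create("scratch/figures", showWarnings = FALSE, recursive = TRUE)
cohort <- local({
  tw <- load_twin_register("scratch/cohort/twins.csv")
  ev <- load_event_register("scratch/cohort/events.csv")
  build_analysis_cohort(tw, ev)
})

cif <- estimate_cif(cohort, by_sex = TRUE, grid = seq(30, 95, by = 1))
write.table(format(as.data.frame(cif), digits = 5), "results/cif_by_sex.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

for (sx in unique(cif$sex)) {
  k <- cif[cif$sex == sx & cif$cause == "case", ]
  c60 <- k$cif[k$age == 60]; c85 <- k$cif[k$age == 85]
  cat(sprintf("%s: CIF(60) = %.4f, CIF(85) = %.4f, fold increase %.1f\n",
              sx, c60, c85, c85 / c60))
}

png("scratch/figures/cif_by_sex.png", width = 900, height = 600)
k <- cif[cif$cause == "case", ]
plot(NA, xlim = range(k$age), ylim = c(0, max(k$cif + 2 * k$se)),
     xlab = "Age (years)", ylab = "Cumulative incidence of THA",
     main = "Cumulative incidence with competing mortality")
cols <- c(male = "red", female = "black")
for (sx in names(cols)) {
  kk <- k[k$sex == sx, ]
  lines(kk$age, kk$cif, col = cols[sx], lwd = 2)
  lines(kk$age, pmax(0, kk$cif - 1.96 * kk$se), col = cols[sx], lty = 3)
  lines(kk$age, kk$cif + 1.96 * kk$se, col = cols[sx], lty = 3)
}
legend("topleft", names(cols), col = cols, lwd = 2, bty = "n")
dev.off()
cat("figure written to scratch/figures/cif_by_sex.png\n")
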