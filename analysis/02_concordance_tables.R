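#!/usr/bin/env Rscript
# Zygosity/sex-stratified concordance and ML tetrachoric correlations on the
# simulated cohort, in the layout of a twin-register concordance table, and
# the same estimator applied to the published complete-pair counts.

library(twinliab)

dir.create("results", showWarnings = FALSE)
cohort <- local({
  tw <- load_twin_register("scratch/cohort/twins.csv")
  ev <- load_event_register("scratch/cohort/events.csv")
  build_analysis_cohort(tw, ev)
})

t2 <- report_table2(cohort)
write.table(format(t2, digits = 4), "results/concordance_table.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
print(t2, digits = 3)

cat("\nMZ tetrachorics exceed DZ tetrachorics in both sexes:",
    all(t2$rho[t2$stratum == "MZM"] > t2$rho[t2$stratum == "DZM"],
        t2$rho[t2$stratum == "MZF"] > t2$rho[t2$stratum == "DZF"], na.rm = TRUE), "\n")

# published complete-pair counts for reference strata
printed <- list(MZM = c(10, 57, 4558), DZM = c(5, 148, 8107),
                MZF = c(9, 72, 4773), DZF = c(5, 148, 7740),
                OSDZ = c(7, 223, 17602))
ref <- do.call(rbind, lapply(names(printed), function(nm) {
  tb <- printed[[nm]]
  est <- tetrachoric(pair_table(tb[1], tb[2], tb[3], nm))
  rates <- concordance_rates(pair_table(tb[1], tb[2], tb[3]))
  data.frame(stratum = nm, n_cc = tb[1], n_cd = tb[2], n_dd = tb[3],
             pairwise = rates$pairwise, probandwise = rates$probandwise,
             rho = est$rho, rho_lo = est$ci95[1], rho_hi = est$ci95[2])
}))
write.table(format(ref, digits = 4), "results/reference_tetrachorics.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("\nML tetrachorics recomputed from the published pair counts:\n")
print(ref[, c("stratum", "pairwise", "probandwise", "rho")], digits = 3)
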