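#!/usr/bin/env Rscript
# Stage 2: single-descriptor QSPR regressions — linear and cubic fits of
# every property on every index, with the statistics panel and the
# actual-versus-predicted tables.

library(topoqspr)

dir.create("results", showWarnings = FALSE)
d <- load_drug_table()

stats_tab <- do.call(rbind, lapply(index_names(), function(ix) qspr_table(d, ix)))
write.csv(stats_tab, "results/qspr_statistics.csv", row.names = FALSE)
cat("wrote results/qspr_statistics.csv (", nrow(stats_tab), "fits )\n")

cat("\n== Headline fits ==\n")
show <- function(ix, prop) {
  row <- stats_tab[stats_tab$index == ix & stats_tab$property == prop &
                     stats_tab$form == "linear", ]
  cat(sprintf("%s ~ %s (linear): y = %.4f + %.4f x, R2 = %.3f, F = %.3f\n",
              prop, ix, row$beta0, row$beta1, row$R_squared, row$F_stat))
}
show("M1", "BP"); show("M1", "MR"); show("H", "MR")

cat("\nBest linear R2 per property:\n")
lin <- stats_tab[stats_tab$form == "linear", ]
for (prop in unique(lin$property)) {
  sub <- lin[lin$property == prop, ]
  best <- sub[which.max(sub$R_squared), ]
  cat(sprintf("  %-3s best index %-3s R2 = %.3f\n", prop, best$index,
              best$R_squared))
}

for (prop in c("BP", "EV", "FP", "MR", "SA", "MV", "P")) {
  tab <- prediction_table(d, prop)
  write.csv(tab, sprintf("results/predictions_%s.csv", prop), row.names = FALSE)
}
cat("\nwrote results/predictions_<property>.csv for the seven properties\n")
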