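#!/usr/bin/env Rscript
# Stage 3: feedforward network (10 -> 32 -> 32 -> 1, ReLU) trained by
# backpropagation on the ten descriptors, one model per property.
# In-sample metrics are reported: the study fits on all 17 drugs.

library(topoqspr)

dir.create("results", showWarnings = FALSE)
d <- load_drug_table()
X <- as.matrix(d[index_names()])

pred_rows <- list(); metric_rows <- list()
for (prop in c("BP", "EV", "FP", "MR", "SA", "MV", "P")) {
  model <- ann_train(X, d[[prop]], ann_config(seed = 0))
  pred <- ann_forward(model, X)
  met <- regression_metrics(d[[prop]], pred)
  cat(sprintf("%-3s: %5d epochs, MSE = %10.3f, MAE = %7.3f, R2 = %.4f\n",
              prop, model$epochs_run, met[["MSE"]], met[["MAE"]],
              met[["R_squared"]]))
  pred_rows[[prop]] <- data.frame(property = prop, name = d$name,
                                  actual = d[[prop]], predicted = round(pred, 4))
  metric_rows[[prop]] <- data.frame(property = prop, t(round(met, 4)))
}
write.csv(do.call(rbind, pred_rows), "results/ann_predictions.csv",
          row.names = FALSE)
write.csv(do.call(rbind, metric_rows), "results/ann_metrics.csv",
          row.names = FALSE)
cat("wrote results/ann_predictions.csv and results/ann_metrics.csv\n")
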