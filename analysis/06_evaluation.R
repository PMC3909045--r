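#!/usr/bin/env Rscript
# Stage 6: evaluation. Strong/weak classification at the reference-D cutoff
# with ROC/AUC per axis, and recovery of the generator's informative
# descriptors by the fitted models.

suppressPackageStartupMessages(library(inktqsar))
out <- "results"

dtab <- read.csv("results/desirability.csv")
class(dtab) <- c("desirability_table", "data.frame")
desc <- read.csv("results/data/descriptors.csv", check.names = FALSE)
x <- as.matrix(desc[, -1]); rownames(x) <- desc[[1]]
x <- prune_constant_descriptors(x)
models <- jsonlite::read_json("results/models.json", simplifyVector = TRUE)

auc_rows <- list()
for (axis in names(models)) {
  d <- axis_d_values(dtab, axis)
  d <- d[names(d) %in% rownames(x)]
  coefs <- unlist(models[[axis]]$pls$coefficients)
  fitted <- drop(x[names(d), names(coefs)] %*% coefs) +
    models[[axis]]$pls$intercept
  labels <- classify_strength(d, d[["C001"]])
  if (length(unique(labels)) < 2) next
  roc <- roc_auc(fitted, labels)
  auc_rows[[axis]] <- data.frame(axis = axis, n_strong = roc$n_pos,
                                 n_weak = roc$n_neg, auc = roc$auc)
  write.csv(data.frame(threshold = roc$thresholds, tpr = roc$tpr, fpr = roc$fpr),
            file.path(out, paste0("roc_", gsub("[^A-Za-z0-9]+", "_", axis), ".csv")),
            row.names = FALSE)
  cat(sprintf("%-13s %d strong vs %d weak | AUC = %.3f\n",
              axis, roc$n_pos, roc$n_neg, roc$auc))
}
write.csv(do.call(rbind, auc_rows), file.path(out, "auc_summary.csv"),
          row.names = FALSE)

# parameter recovery of the stepwise models against simulated ground truth
truth <- jsonlite::read_json("results/data/ground_truth.json", simplifyVector = TRUE)
cat("\nStepwise-MLR recovery of informative descriptors:\n")
for (axis in names(models)) {
  sel <- unlist(models[[axis]]$mlr$selected)
  tp <- length(intersect(sel, truth$informative_names))
  cat(sprintf("%-13s selected %d | informative recovered %d/%d | false %d\n",
              axis, length(sel), tp, length(truth$informative_names),
              length(sel) - tp))
}
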