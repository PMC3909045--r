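#!/usr/bin/env Rscript
# Stage 5: structure-immune models. For each desirability axis, a stepwise
# MLR (probability-of-F 0.05 to enter / 0.10 to remove) and a PLS model with
# the component count chosen by seven-fold cross-validated Q2.

suppressPackageStartupMessages(library(inktqsar))
out <- "results"

dtab <- read.csv("results/desirability.csv")
class(dtab) <- c("desirability_table", "data.frame")
desc <- read.csv("results/data/descriptors.csv", check.names = FALSE)
x <- as.matrix(desc[, -1]); rownames(x) <- desc[[1]]
x <- prune_constant_descriptors(x)

models <- list()
for (axis in desirability_axes()) {
  d <- axis_d_values(dtab, axis)
  d <- d[names(d) %in% rownames(x)]
  if (length(d) < 10) { cat(axis, ": too few compounds, skipped\n"); next }
  xa <- x[names(d), ]
  mlr <- suppressWarnings(stepwise_mlr_fit(xa, d))
  nc <- choose_pls_ncomp(xa, d, max_components = 6, k = 7, seed = 1)
  pls <- pls_fit(xa, d, nc$n_components)
  q2_mlr <- if (length(mlr$selected))
    kfold_q2(xa, d, mlr_spec(), k = 7, seed = 1)$q2 else NA_real_
  models[[axis]] <- list(
    axis = axis, n = length(d),
    mlr = list(selected = mlr$selected,
               coefficients = as.list(mlr$coefficients),
               intercept = mlr$intercept, r2 = mlr$r2, q2 = q2_mlr),
    pls = list(n_components = nc$n_components, r2 = pls$r2, q2 = nc$q2,
               coefficients = as.list(pls$coefficients),
               intercept = pls$intercept))
  cat(sprintf("%-13s n = %3d | MLR: R2 = %.3f (%d terms) | PLS: R2 = %.3f, Q2 = %.3f (%d comp)\n",
              axis, length(d), mlr$r2, length(mlr$selected),
              pls$r2, nc$q2, nc$n_components))
}
jsonlite::write_json(models, file.path(out, "models.json"),
                     auto_unbox = TRUE, digits = NA)
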