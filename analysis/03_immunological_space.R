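#!/usr/bin/env Rscript
# Stage 3: the immunological space. Intra- and inter-variability of the
# test-models, cross-model agreement, and the four Th1/Th2 desirability
# axes per compound.

suppressPackageStartupMessages(library(inktqsar))
out <- "results"

norm <- read.csv("results/normalized_per_study.csv")
vr <- variability_report(norm)
write.csv(vr$cells, file.path(out, "variability_cells.csv"), row.names = FALSE)
write.csv(vr$cross_model, file.path(out, "variability_cross_model.csv"),
          row.names = FALSE)
print(vr)

mat <- aggregate_replicates(norm)
dtab <- suppressWarnings(desirability_profiles(mat))
write.csv(as.data.frame(dtab), file.path(out, "desirability.csv"),
          row.names = FALSE)

cat("\nCompounds with a complete D-value per axis:\n")
for (a in desirability_axes()) {
  d <- axis_d_values(dtab, a)
  cat(sprintf("  %-13s n = %3d | reference D = %.3f | max D = %.3f\n",
              a, length(d), d[["C001"]], max(d)))
}
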