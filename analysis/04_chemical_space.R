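#!/usr/bin/env Rscript
# Stage 4: the chemical space. Constant-descriptor pruning, UV scaling,
# PCA score space and average-linkage (UPGMA) clustering of the compounds.

suppressPackageStartupMessages(library(inktqsar))
out <- "results"

desc <- read.csv("results/data/descriptors.csv", check.names = FALSE)
x <- as.matrix(desc[, -1]); rownames(x) <- desc[[1]]
xp <- prune_constant_descriptors(x)
cat(sprintf("Removed %d constant descriptor(s): %s\n",
            length(attr(xp, "removed")),
            paste(attr(xp, "removed"), collapse = ", ")))

pca <- pca_scores(xp, n_components = 2)
write.csv(data.frame(compound_id = rownames(pca$scores), pca$scores,
                     check.names = FALSE),
          file.path(out, "pca_scores.csv"), row.names = FALSE)
cat(sprintf("PCA: t1 explains %.1f%%, t2 %.1f%% of descriptor variance.\n",
            100 * pca$explained[1], 100 * pca$explained[2]))

hc <- hca_average_linkage(xp)
write_dendrogram_newick(hc, file.path(out, "dendrogram.nwk"))
write.csv(merge_table(hc), file.path(out, "hca_merges.csv"), row.names = FALSE)
cat(sprintf("UPGMA dendrogram: %d merges, final height %.2f.\n",
            length(hc$height), max(hc$height)))
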