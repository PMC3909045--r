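#!/usr/bin/env Rscript
# Stage 2: ingest the simulated studies, normalize every response to the
# alpha-GalCer reference at its per-study peak condition, average replicate
# studies into one result per (compound, test-system, marker), and summarize
# the dataset composition next to the published frequency table.

suppressPackageStartupMessages(library(inktqsar))
out <- "results"

records <- read_response_table("results/data/responses.csv")
norm <- suppressWarnings(normalize_to_reference(records, "C001"))
mat <- aggregate_replicates(norm)
write.csv(data.frame(compound_id = rownames(mat$values), mat$values,
                     check.names = FALSE),
          file.path(out, "relative_responses.csv"), row.names = FALSE)
write.csv(norm, file.path(out, "normalized_per_study.csv"), row.names = FALSE)

freq <- summarize_frequencies(mat)
write.csv(as.data.frame(freq), file.path(out, "frequencies_synthetic.csv"),
          row.names = FALSE)
pub <- summarize_frequencies(table1_counts())
write.csv(as.data.frame(pub), file.path(out, "frequencies_published.csv"),
          row.names = FALSE)

cat(sprintf("Aggregated %d results over %d compounds (published set: %d over 333).\n",
            attr(freq, "grand_total"), nrow(mat$values), attr(pub, "grand_total")))
cat("Per-test-model shares, synthetic vs published:\n")
print(merge(system_shares(freq), system_shares(pub),
            by = "test_system", suffixes = c("_synthetic", "_published")))
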