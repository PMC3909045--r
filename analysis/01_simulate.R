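#!/usr/bin/env Rscript
# Stage 1: simulate a literature-scale glycolipid dataset with known truth.
#
# 333 compounds (the reference alpha-GalCer first), 100 chemical descriptors
# in correlated blocks with 8 constant columns, and multi-study cytokine
# measurements whose per-cell sparsity follows the published
# measurement-frequency table. Ground truth: 6 informative descriptors with
# opposite-signed effects on IFN-g vs IL-4, so true Th1/Th2 polarizers exist.

suppressPackageStartupMessages(library(inktqsar))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(n_compounds = 333, n_descriptors = 100,
                        n_informative = 6, n_constant = 8,
                        coefficient_scale = 0.45, study_noise_cv = 0.35,
                        n_studies_mean = 2, seed = 20140131)
cs <- generate_chemical_space(cfg)
resp <- generate_response_studies(cs$descriptors, cs$truth, cfg)

write.csv(resp, file.path(out, "responses.csv"), row.names = FALSE)
write.csv(data.frame(compound_id = rownames(cs$descriptors), cs$descriptors,
                     check.names = FALSE),
          file.path(out, "descriptors.csv"), row.names = FALSE)
jsonlite::write_json(list(reference_compound_id = cs$truth$reference_compound_id,
                          informative_names = cs$truth$informative_names,
                          beta_base = cs$truth$beta_base,
                          coefficients = cs$truth$coefficients),
                     file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("Simulated %d raw records for %d compounds (%d studies).\n",
            nrow(resp), cfg$n_compounds, length(unique(resp$study_id))))
cat(sprintf("Informative descriptors: %s\n",
            paste(cs$truth$informative_names, collapse = ", ")))
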