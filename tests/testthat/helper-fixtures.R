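# Shared in-code fixtures for the test suite.

validate_df <- function(df) inktqsar:::validate_response_records(df)

# a tiny hand-written response table: one study, one cell, three compounds
tiny_response_df <- function() {
  data.frame(
    compound_id = c("REF", "A", "B"),
    study_id = "s1",
    species = "mice", setting = "in_vivo", presentation = "",
    marker = "IFN-g",
    dose = 100, dose_unit = "ng/mL", time = 24, time_unit = "h",
    value = c(125, 250, 0),
    stringsAsFactors = FALSE)
}

write_tiny_response_csv <- function(df = tiny_response_df()) {
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  f
}

# dense synthetic dataset for model-level tests: every modelled cell
# measured for every compound
dense_config <- function(seed = 1L, n_compounds = 80L, study_noise_cv = 0.3,
                         n_studies_mean = 1, ...) {
  generator_config(n_compounds = n_compounds, n_descriptors = 20L,
                   n_informative = 4L, n_constant = 2L,
                   study_noise_cv = study_noise_cv,
                   n_studies_mean = n_studies_mean,
                   measure_prob = 1, seed = seed, ...)
}
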