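test_that("chemical space generation forces the configured structure", {
  cfg <- generator_config(n_compounds = 60, n_descriptors = 25,
                          n_informative = 5, n_constant = 5, seed = 11)
  cs <- generate_chemical_space(cfg)
  expect_equal(dim(cs$descriptors), c(60L, 25L))
  expect_equal(sum(apply(cs$descriptors, 2, var) == 0), 5L)
  # informative coefficients nonzero exactly on the informative set
  expect_true(all(cs$truth$beta_base[cs$truth$informative_indices] != 0))
  expect_true(all(cs$truth$beta_base[-cs$truth$informative_indices] == 0))
  # reference compound carries no informative signal
  expect_true(all(cs$descriptors[1, cs$truth$informative_indices] == 0))

  cs2 <- generate_chemical_space(cfg)
  expect_identical(cs$descriptors, cs2$descriptors)
  expect_identical(cs$truth, cs2$truth)
})

test_that("informative block reaches the configured correlation", {
  cfg <- generator_config(n_compounds = 200, n_descriptors = 30,
                          n_informative = 5, n_constant = 0,
                          block_correlation = 0.8, seed = 5)
  cs <- generate_chemical_space(cfg)
  block <- cs$descriptors[-1, cs$truth$informative_indices]  # drop zeroed reference row
  cm <- cor(block)
  mean_r <- mean(abs(cm[upper.tri(cm)]))
  expect_gt(mean_r, 0.5)
  expect_gt(mean_r, 0.8 - 0.15)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_informative = 30, n_descriptors = 20),
               "n_informative")
  expect_error(generator_config(n_constant = -1), "n_constant")
  expect_error(generator_config(block_correlation = 1), "block_correlation")
  expect_error(generator_config(study_noise_cv = -0.1), "study_noise_cv")
})

test_that("noiseless responses equal exp(x beta) after normalization", {
  cfg <- dense_config(seed = 2, n_compounds = 20, study_noise_cv = 0,
                      systems = "mice/in vivo", markers = c("IFN-g", "IL-4"))
  cs <- generate_chemical_space(cfg)
  resp <- generate_response_studies(cs$descriptors, cs$truth, cfg)
  norm <- normalize_to_reference(resp, cs$truth$reference_compound_id)
  for (m in c("IFN-g", "IL-4")) {
    sub <- norm[norm$marker == m, ]
    beta <- cs$truth$coefficients[[paste0("mice/in vivo|", m)]]
    expected <- exp(drop(cs$descriptors[sub$compound_id, ] %*% beta))
    expect_equal(sub$normalized, unname(expected), tolerance = 1e-12)
  }
  # reference is exactly 1 in every study
  expect_true(all(norm$normalized[norm$compound_id == "C001"] == 1))
})

test_that("zero coefficients and zero noise give unit responses everywhere", {
  cfg <- dense_config(seed = 3, n_compounds = 12, study_noise_cv = 0,
                      coefficient_scale = 0,
                      systems = "human/in vitro/cell-cell", markers = "IL-4")
  cs <- generate_chemical_space(cfg)
  resp <- generate_response_studies(cs$descriptors, cs$truth, cfg)
  norm <- normalize_to_reference(resp, "C001")
  expect_true(all(abs(norm$normalized - 1) < 1e-12))
})

test_that("lognormal study noise reproduces the configured CV", {
  cfg <- generator_config(n_compounds = 1000, n_descriptors = 5,
                          n_informative = 2, n_constant = 0,
                          coefficient_scale = 0.3,
                          study_noise_cv = 0.5, n_studies_mean = 5,
                          measure_prob = 1,
                          systems = "human/in vitro/cell-plate",  # noise factor 1
                          markers = "IFN-g", seed = 9)
  cs <- generate_chemical_space(cfg)
  resp <- generate_response_studies(cs$descriptors, cs$truth, cfg)
  norm <- normalize_to_reference(resp, "C001")
  rsd <- intra_rsd(norm)
  expect_gt(nrow(rsd), 900)
  expect_equal(median(rsd$rsd), 50, tolerance = 15 / 50)
})

test_that("measurement frequencies converge to the configured probabilities", {
  cfg <- generator_config(n_compounds = 501, n_descriptors = 5,
                          n_informative = 1, n_constant = 0,
                          measure_prob = 0.3, n_studies_mean = 1, seed = 21)
  cs <- generate_chemical_space(cfg)
  resp <- generate_response_studies(cs$descriptors, cs$truth, cfg)
  u <- unique(resp[resp$compound_id != "C001",
                   c("compound_id", "species", "setting", "presentation", "marker")])
  # 500 eligible compounds x 20 cells = 10,000 Bernoulli draws
  expect_equal(nrow(u) / (500 * 20), 0.3, tolerance = 0.03 / 0.3)
})

test_that("fixture suite is reproducible and self-consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_fixture_suite(d1, seed = 1)
  m2 <- generate_fixture_suite(d2, seed = 1)
  expect_identical(lapply(m1$files, `[[`, "md5"), lapply(m2$files, `[[`, "md5"))
  for (f in m1$files) expect_true(file.exists(file.path(d1, f$file)))
  counts <- read.csv(file.path(d1, "frequency_counts.csv"))
  expect_equal(sum(counts$count), 851)
  # fixture stays small
  expect_lte(nrow(read.csv(file.path(d1, "descriptors.csv"))), 50)
})

test_that("noise_cv_for_r2 hits the requested log-scale R2", {
  cfg <- dense_config(seed = 4, n_compounds = 2000, study_noise_cv = 0,
                      systems = "mice/in vivo", markers = "IFN-g")
  cs <- generate_chemical_space(cfg)
  beta <- cs$truth$coefficients[["mice/in vivo|IFN-g"]]
  cv <- noise_cv_for_r2(cs$descriptors, beta, r2 = 0.8)
  sig <- drop(cs$descriptors %*% beta)
  set.seed(99)
  noise <- rnorm(length(sig), 0, sqrt(log1p(cv^2)))
  r2 <- var(sig) / var(sig + noise)
  expect_equal(r2, 0.8, tolerance = 0.05)
})
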