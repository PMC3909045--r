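test_that("response tables parse with vocabulary normalization", {
  f <- write_tiny_response_csv()
  rec <- read_response_table(f)
  expect_equal(nrow(rec), 3L)
  expect_equal(unique(rec$test_system), "mice/in vivo")
  expect_equal(unique(rec$marker), "IFN-g")

  # case/format-normalized marker and test-system spellings
  df <- tiny_response_df()
  df$marker <- c("il4", "IL-4", "Il 4")
  df$species <- "Mouse"; df$setting <- "in vitro"; df$presentation <- "Cell-Cell"
  rec2 <- read_response_table(write_tiny_response_csv(df))
  expect_equal(unique(rec2$marker), "IL-4")
  expect_equal(unique(rec2$test_system), "mice/in vitro/cell-cell")
})

test_that("malformed rows are rejected with their line numbers", {
  df <- tiny_response_df()
  df$value[2] <- "NA"
  expect_error(read_response_table(write_tiny_response_csv(df)), "line\\(s\\) 3")
  df <- tiny_response_df()
  df$marker[3] <- "TNF-a"
  expect_error(read_response_table(write_tiny_response_csv(df)),
               "unknown marker at data line\\(s\\) 4")
  df <- tiny_response_df()[0, ]
  expect_error(read_response_table(write_tiny_response_csv(df)), "empty")
})

test_that("reference condition selection is argmax with lowest-dose ties", {
  df <- rbind(tiny_response_df(), tiny_response_df(), tiny_response_df())
  df$dose <- rep(c(10, 100, 1000), each = 3)
  df$value[df$compound_id == "REF"] <- c(10, 50, 30)
  rec <- validate_df(df)
  cond <- select_reference_condition(rec, "mice/in vivo", "IFN-g", "s1", "REF")
  expect_equal(cond$dose, 100)
  # tie in the maxima -> lowest dose
  df$value[df$compound_id == "REF"] <- c(50, 50, 30)
  cond <- select_reference_condition(validate_df(df), "mice/in vivo", "IFN-g",
                                     "s1", "REF")
  expect_equal(cond$dose, 10)
  # reference absent -> NULL with warning
  expect_warning(
    out <- select_reference_condition(rec, "mice/in vivo", "IL-4", "s1", "REF"),
    "absent")
  expect_null(out)
})

test_that("normalization divides by the reference at its peak condition", {
  rec <- validate_df(tiny_response_df())
  norm <- normalize_to_reference(rec, "REF")
  expect_equal(norm$normalized[norm$compound_id == "A"], 2.0)   # 250 / 125
  expect_equal(norm$normalized[norm$compound_id == "REF"], 1.0)
  expect_equal(norm$normalized[norm$compound_id == "B"], 0.0)

  # zero reference response drops the cell
  df <- tiny_response_df(); df$value[1] <- 0
  expect_error(expect_warning(normalize_to_reference(validate_df(df), "REF"),
                              "zero"),
               "no study retained")

  # idempotence: renormalizing an already-normalized table is the identity
  df2 <- tiny_response_df(); df2$value <- norm$normalized[match(df2$compound_id, norm$compound_id)]
  norm2 <- normalize_to_reference(validate_df(df2), "REF")
  expect_equal(norm2$normalized[order(norm2$compound_id)],
               norm$normalized[order(norm$compound_id)])
})

test_that("replicate aggregation is the unweighted mean, permutation invariant", {
  norm <- data.frame(compound_id = c("A", "A", "REF"),
                     study_id = c("s1", "s2", "s1"),
                     test_system = "mice/in vivo", marker = "IFN-g",
                     normalized = c(1, 3, 1))
  mat <- aggregate_replicates(norm)
  expect_equal(unname(mat$values["A", 1]), 2)
  expect_equal(unname(mat$n_sources["A", 1]), 2L)
  expect_equal(unname(mat$n_sources["REF", 1]), 1L)
  mat2 <- aggregate_replicates(norm[c(3, 2, 1), ])
  expect_identical(mat$values, mat2$values)
})

test_that("aggregated noiseless values equal the generator ground truth", {
  cfg <- dense_config(seed = 6, n_compounds = 15, study_noise_cv = 0,
                      n_studies_mean = 2,
                      systems = "mice/in vitro/cell-cell", markers = "IFN-g")
  cs <- generate_chemical_space(cfg)
  resp <- generate_response_studies(cs$descriptors, cs$truth, cfg)
  mat <- aggregate_replicates(normalize_to_reference(resp, "C001"))
  beta <- cs$truth$coefficients[["mice/in vitro/cell-cell|IFN-g"]]
  expected <- exp(drop(cs$descriptors[rownames(mat$values), ] %*% beta))
  expect_equal(unname(mat$values[, 1]), unname(expected), tolerance = 1e-10)
})

test_that("frequency summary reproduces the published dataset composition", {
  freq <- summarize_frequencies(table1_counts())
  expect_equal(attr(freq, "grand_total"), 851)
  expect_equal(sum(freq$percent), 100, tolerance = 0.05 / 100)
  get <- function(s, m) freq$percent[freq$test_system == s & freq$marker == m]
  expect_equal(get("mice/in vitro/cell-cell", "IL-2"), 10.22)
  expect_equal(get("human/in vitro/cell-cell", "IL-13"), 6.58)
  shares <- system_shares(freq)
  expect_equal(shares$percent[shares$test_system == "human/in vitro/cell-cell"], 34.31)
  expect_equal(shares$percent[shares$test_system == "mice/in vitro/cell-cell"], 28.67)
  expect_equal(shares$percent[shares$test_system == "mice/in vivo"], 27.85)
})

test_that("frequency summary counts one result per non-missing cell", {
  norm <- data.frame(compound_id = c("A", "A", "B"),
                     study_id = c("s1", "s2", "s1"),
                     test_system = c("mice/in vivo", "mice/in vivo",
                                     "human/in vitro/cell-cell"),
                     marker = c("IFN-g", "IFN-g", "IL-4"),
                     normalized = c(1, 3, 2))
  freq <- summarize_frequencies(aggregate_replicates(norm))
  expect_equal(attr(freq, "grand_total"), 2L)  # A's two studies -> one result
  expect_setequal(freq$percent[freq$count > 0], c(50, 50))

  single <- aggregate_replicates(norm[3, ])
  f1 <- summarize_frequencies(single)
  expect_equal(f1$percent[f1$count > 0], 100)
})
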