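test_that("stepwise MLR finds a single strong predictor and nothing else", {
  set.seed(20)
  x <- matrix(rnorm(100 * 11), 100, 11, dimnames = list(NULL, paste0("X", 1:11)))
  y <- 2 * x[, 3] + rnorm(100, 0, 0.01)
  m <- stepwise_mlr_fit(x, y)
  expect_equal(m$selected, "X3")
  expect_equal(unname(m$coefficients), 2, tolerance = 0.01)
  expect_gt(m$r2, 0.999)
  expect_equal(m$trace$action[1], "enter")
})

test_that("stepwise MLR rarely selects anything from pure noise", {
  empty <- 0L
  for (s in 1:100) {
    set.seed(s)
    x <- matrix(rnorm(100 * 10), 100, 10)
    y <- rnorm(100)
    m <- suppressWarnings(stepwise_mlr_fit(x, y))
    empty <- empty + (length(m$selected) == 0L)
  }
  expect_gte(empty, 95L)
})

test_that("a duplicated column is never co-selected (collinearity guard)", {
  set.seed(21)
  x <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("X", 1:5)))
  x <- cbind(x, X3dup = x[, 3])
  y <- 3 * x[, 3] + rnorm(60, 0, 0.1)
  m <- stepwise_mlr_fit(x, y)
  expect_false(all(c("X3", "X3dup") %in% m$selected))
  expect_true(any(c("X3", "X3dup") %in% m$selected))
})

test_that("stepwise accepts p_enter < p_remove only and respects row minimum", {
  x <- matrix(rnorm(50 * 3), 50, 3)
  expect_error(stepwise_mlr_fit(x, rnorm(50), p_enter = 0.2, p_remove = 0.1))
  expect_error(stepwise_mlr_fit(x[1:5, ], rnorm(5)), ">= 10")
})

test_that("PLS fits an exact single-direction response with one component", {
  set.seed(22)
  x1 <- rnorm(30)
  x <- cbind(a = x1, b = 2 * x1 + 1)    # one latent direction after scaling
  y <- 3 * x1 + 0.5
  m <- pls_fit(x, y, 1)
  expect_equal(m$r2, 1.0, tolerance = 1e-8)
  expect_equal(unname(predict(m, x)), unname(y), tolerance = 1e-8)
  expect_error(pls_fit(x, rep(1, 30), 1), "zero variance")
  expect_error(pls_fit(x, y, 5), "n_components")
})

test_that("PLS with full components reproduces ordinary least squares", {
  set.seed(23)
  x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("d", 1:6)))
  y <- drop(x %*% runif(6, -1, 1)) + rnorm(40, 0, 0.5)
  m <- pls_fit(x, y, 6)
  ols <- lm(y ~ x)
  expect_lt(max(abs(predict(m, x) - unname(fitted(ols)))), 1e-6)
  # successive score vectors orthogonal
  g <- crossprod(m$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("PLS coefficients are invariant under row permutation", {
  set.seed(24)
  x <- matrix(rnorm(35 * 5), 35, 5, dimnames = list(NULL, paste0("d", 1:5)))
  y <- drop(x %*% c(1, -1, 0.5, 0, 0)) + rnorm(35, 0, 0.3)
  perm <- sample(35)
  m1 <- pls_fit(x, y, 3)
  m2 <- pls_fit(x[perm, ], y[perm], 3)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-10)
})

test_that("cross-validated Q2 behaves at its defining limits", {
  set.seed(25)
  x <- matrix(rnorm(70 * 4), 70, 4, dimnames = list(NULL, paste0("d", 1:4)))
  y <- drop(x %*% c(2, -1, 0, 0))          # noiseless
  expect_equal(kfold_q2(x, y, pls_spec(4), k = 7, seed = 1)$q2, 1.0,
               tolerance = 1e-6)

  # intercept-only prediction gives Q2 near zero
  mean_spec <- function(x, y) structure(list(mu = mean(y)), class = "mean_model")
  assign("predict.mean_model",
         function(object, newdata, ...) rep(object$mu, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.mean_model", envir = globalenv()), add = TRUE)
  set.seed(26)
  y2 <- rnorm(200)
  x2 <- matrix(rnorm(200 * 3), 200, 3)
  expect_equal(kfold_q2(x2, y2, mean_spec, k = 7, seed = 1)$q2, 0,
               tolerance = 0.1)

  # permuted response: no predictive ability
  set.seed(27)
  yp <- sample(y)
  expect_lte(kfold_q2(x, yp, pls_spec(2), k = 7, seed = 1)$q2, 0.1)

  expect_error(kfold_q2(x, y, pls_spec(1), k = 1), "k must be")
})

test_that("Q2 never exceeds training R2 across random instances", {
  set.seed(28)
  for (i in 1:50) {
    n <- sample(30:60, 1); p <- sample(4:8, 1)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", 1:p)))
    beta <- rnorm(p) * rbinom(p, 1, 0.5)
    y <- drop(x %*% beta) + rnorm(n, 0, 1)
    nc <- sample(seq_len(min(3, p)), 1)
    r2 <- pls_fit(x, y, nc)$r2
    q2 <- kfold_q2(x, y, pls_spec(nc), k = 7, seed = i)$q2
    expect_lte(q2, r2 + 1e-10)
  }
})

test_that("component choice stops when Q2 stops improving", {
  set.seed(29)
  x <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("d", 1:8)))
  y <- drop(x %*% c(2, -2, rep(0, 6))) + rnorm(60, 0, 0.4)
  ch <- choose_pls_ncomp(x, y, max_components = 8, seed = 1)
  expect_lte(ch$n_components, 4L)
  expect_gt(ch$q2, 0.8)
})

test_that("stepwise MLR recovers informative descriptors from generated data", {
  cfg <- generator_config(n_compounds = 150, n_descriptors = 50,
                          n_informative = 5, n_constant = 0,
                          n_studies_mean = 1, measure_prob = 1,
                          systems = "mice/in vivo", markers = "IFN-g",
                          seed = 31)
  cs <- generate_chemical_space(cfg)
  beta <- cs$truth$coefficients[["mice/in vivo|IFN-g"]]
  cfg$study_noise_cv <- noise_cv_for_r2(cs$descriptors, beta, 0.8)
  resp <- generate_response_studies(cs$descriptors, cs$truth, cfg)
  mat <- aggregate_replicates(normalize_to_reference(resp, "C001"))
  y <- log(mat$values[, 1])
  m <- stepwise_mlr_fit(cs$descriptors[names(y), ], y)
  rec <- parameter_recovery_report(cs$truth, m)
  expect_gte(rec$true_positives, 4L)
  expect_lte(rec$false_inclusions, 2L)
  expect_equal(rec$sign_agreement, 1.0)
  expect_gt(rec$coef_rank_correlation, 0)
})

test_that("predictions generalize to held-out compounds", {
  cfg <- dense_config(seed = 32, n_compounds = 150, study_noise_cv = 0,
                      systems = "mice/in vivo", markers = "IFN-g")
  cs <- generate_chemical_space(cfg)
  beta <- cs$truth$coefficients[["mice/in vivo|IFN-g"]]
  cfg$study_noise_cv <- noise_cv_for_r2(cs$descriptors, beta, 0.8)
  resp <- generate_response_studies(cs$descriptors, cs$truth, cfg)
  mat <- aggregate_replicates(normalize_to_reference(resp, "C001"))
  y <- log(mat$values[, 1])
  x <- prune_constant_descriptors(cs$descriptors[names(y), ])
  train <- seq_len(100); test <- setdiff(seq_along(y), train)
  m <- pls_fit(x[train, ], y[train], 3)
  pred <- predict(m, x[test, ])
  truth_test <- drop(cs$descriptors[names(y)[test], ] %*% beta)
  expect_gte(cor(pred, truth_test, method = "spearman"), 0.7)
  # training rows reproduce fitted values; missing columns are reported
  expect_equal(unname(predict(m, x[train, ])),
               unname(predict(m, x)[train]))
  expect_error(predict(m, x[, 1:3]), "missing descriptor")
})

test_that("desirability predictions clip to the feasible range", {
  set.seed(33)
  x <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(paste0("C", 1:40), paste0("d", 1:4)))
  y <- 0.5 + 0.5 * x[, 1]
  m <- pls_fit(x, y, 1)
  pred <- predict_desirability(m, x)
  expect_true(all(pred >= 0.1 & pred <= 0.9))
  expect_named(pred, rownames(x))
})
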