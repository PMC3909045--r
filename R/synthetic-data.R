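#' Configuration for the synthetic structure-immune data generator
#'
#' The generator emulates the structure of a literature-curated glycolipid
#' dataset: a compound-by-descriptor matrix with correlated descriptor blocks
#' and constant columns, and sparse multi-study cytokine measurements per
#' (test-system, marker) cell with multiplicative (lognormal) inter-study
#' noise on the normalized-response scale. Ground truth is a linear
#' descriptor effect on the log of the normalized response, with
#' opposite-signed IFN-g / IL-4 coefficients so that compounds are genuine
#' Th1/Th2 polarizers.
#'
#' @param n_compounds number of compounds (the first is the reference,
#'   alpha-GalCer, whose informative descriptors are zeroed so its expected
#'   normalized response is 1 in every cell).
#' @param n_descriptors total descriptor columns.
#' @param n_informative number of descriptors with nonzero effect (first
#'   correlated block).
#' @param n_constant number of zero-variance columns, interspersed among the
#'   descriptors.
#' @param block_correlation target within-block pairwise correlation of the
#'   correlated descriptor blocks, in [0, 1).
#' @param coefficient_scale multiplier on the informative coefficients
#'   (|beta| drawn uniformly in 0.8-1.2 times this, random signs).
#' @param study_noise_cv coefficient of variation of the lognormal
#'   inter-study noise applied to the normalized response.
#' @param n_studies_mean mean number of independent studies per measured
#'   (compound, cell): counts are `1 + Poisson(n_studies_mean - 1)`.
#' @param measure_prob per-cell probability that a compound is measured at
#'   all in a given (test-system, marker) cell. Named numeric vector over
#'   `cell_label(test_system, marker)`; the default reproduces the sparsity
#'   of the published measurement-frequency table (count / 333 per cell).
#'   A single unnamed number is recycled to all 20 cells.
#' @param systems,markers subsets of [test_systems()] / [markers()] to
#'   generate; default all.
#' @param seed integer; fully determines the generated data.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_compounds = 150,
                             n_descriptors = 50,
                             n_informative = 5,
                             n_constant = 3,
                             block_correlation = 0.5,
                             coefficient_scale = 0.5,
                             study_noise_cv = 0.35,
                             n_studies_mean = 2,
                             measure_prob = NULL,
                             systems = test_systems(),
                             markers = inktqsar::markers(),
                             seed = 1L) {
  stopifnot(n_compounds >= 2, n_descriptors >= 1)
  if (n_informative > n_descriptors - n_constant)
    stop("n_informative must not exceed the number of non-constant descriptors")
  if (n_constant < 0 || n_constant >= n_descriptors)
    stop("n_constant must be in [0, n_descriptors)")
  if (block_correlation < 0 || block_correlation >= 1)
    stop("block_correlation must be in [0, 1)")
  if (study_noise_cv < 0) stop("study_noise_cv must be >= 0")
  if (n_studies_mean < 1) stop("n_studies_mean must be >= 1")
  if (!all(systems %in% test_systems())) stop("unknown test system in 'systems'")
  if (!all(markers %in% inktqsar::markers())) stop("unknown marker in 'markers'")
  cells <- as.vector(outer(systems, markers, cell_label))
  if (is.null(measure_prob)) {
    mp <- default_measure_prob()[cells]
  } else if (is.null(names(measure_prob))) {
    stopifnot(length(measure_prob) == 1L, measure_prob >= 0, measure_prob <= 1)
    mp <- stats::setNames(rep(measure_prob, length(cells)), cells)
  } else {
    if (!all(cells %in% names(measure_prob)))
      stop("measure_prob must name every generated (test-system, marker) cell")
    mp <- measure_prob[cells]
  }
  structure(list(
    n_compounds = as.integer(n_compounds),
    n_descriptors = as.integer(n_descriptors),
    n_informative = as.integer(n_informative),
    n_constant = as.integer(n_constant),
    block_correlation = block_correlation,
    coefficient_scale = coefficient_scale,
    study_noise_cv = study_noise_cv,
    n_studies_mean = n_studies_mean,
    measure_prob = mp,
    systems = systems,
    markers = markers,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Per-cell measurement probabilities derived from the published
# measurement-frequency table: count / 333 compounds.
default_measure_prob <- function() {
  counts <- table1_counts()
  p <- counts$count / 333
  stats::setNames(pmin(p, 1), cell_label(counts$test_system, counts$marker))
}

# per-system multipliers on study_noise_cv: the human in-vitro cell-cell
# assay is the most reproducible across groups, mice systems noisier
system_noise_factor <- c(
  "mice/in vivo" = 1.3,
  "mice/in vitro/cell-cell" = 1.1,
  "mice/in vitro/cell-plate" = 1.1,
  "human/in vitro/cell-cell" = 0.7,
  "human/in vitro/cell-plate" = 1.0)

# per-system scaling of the descriptor effect: in-vivo responses are the
# most polarized, plate-bound presentation attenuates
system_effect_scale <- c(
  "mice/in vivo" = 1.3,
  "mice/in vitro/cell-cell" = 1.0,
  "mice/in vitro/cell-plate" = 0.8,
  "human/in vitro/cell-cell" = 1.0,
  "human/in vitro/cell-plate" = 0.8)

# Th1/Th2 polarization: the same latent descriptor effect drives IFN-g up
# and IL-4/IL-13 down (or vice versa), creating opposite-signed coefficients
marker_sign <- c("IFN-g" = 1, "IL-4" = -1, "IL-2" = 0.5, "IL-13" = -0.5)

#' Generate a synthetic chemical descriptor matrix with known ground truth
#'
#' Descriptors are organized in correlated blocks (one shared latent factor
#' per block, loading `sqrt(block_correlation)`), the first block being the
#' informative one; `n_constant` zero-variance columns are interspersed at
#' seeded random positions. The reference compound's informative descriptors
#' are set to zero so that its expected normalized response is exactly 1.
#'
#' @param config a [generator_config()].
#' @return A list with `descriptors` (numeric matrix, compounds x
#'   descriptors, row/col named) and `truth` (a `ground_truth` list:
#'   `coefficients` mapping each cell label to a descriptor-length vector,
#'   `reference_compound_id`, `informative_indices`, `beta_base`).
#' @export
generate_chemical_space <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_compounds
  p <- config$n_descriptors
  p_var <- p - config$n_constant
  rho <- config$block_correlation

  # variable columns: blocks of 5 sharing a latent factor (first block =
  # informative, sized n_informative)
  sizes <- c(config$n_informative)
  while (sum(sizes) < p_var) sizes <- c(sizes, min(5L, p_var - sum(sizes)))
  sizes <- sizes[sizes > 0]
  xs <- vector("list", length(sizes))
  for (b in seq_along(sizes)) {
    z <- stats::rnorm(n)
    eps <- matrix(stats::rnorm(n * sizes[b]), n, sizes[b])
    xs[[b]] <- sqrt(rho) * z + sqrt(1 - rho) * eps
  }
  xvar <- do.call(cbind, xs)

  const_pos <- if (config$n_constant > 0) sort(sample.int(p, config$n_constant)) else integer(0)
  var_pos <- setdiff(seq_len(p), const_pos)
  x <- matrix(0, n, p)
  x[, var_pos] <- xvar
  x[, const_pos] <- rep(1, n)  # zero variance

  compound_ids <- sprintf("C%03d", seq_len(n))
  ref_id <- compound_ids[1L]
  informative <- var_pos[seq_len(config$n_informative)]
  x[1L, informative] <- 0  # reference: zero informative contribution
  dimnames(x) <- list(compound_ids, sprintf("D%03d", seq_len(p)))

  beta_base <- numeric(p)
  beta_base[informative] <- sample(c(-1, 1), config$n_informative, replace = TRUE) *
    stats::runif(config$n_informative, 0.8, 1.2) * config$coefficient_scale

  coefs <- list()
  for (s in config$systems) for (m in config$markers) {
    coefs[[cell_label(s, m)]] <-
      beta_base * system_effect_scale[[s]] * marker_sign[[m]]
  }

  truth <- structure(list(
    coefficients = coefs,
    reference_compound_id = ref_id,
    informative_indices = informative,
    informative_names = colnames(x)[informative],
    descriptor_names = colnames(x),
    beta_base = beta_base
  ), class = "ground_truth")

  list(descriptors = x, truth = truth)
}

#' Generate multi-study cytokine response records
#'
#' For every (compound, test-system, marker) cell measured (per-cell
#' Bernoulli with `measure_prob`), `1 + Poisson(n_studies_mean - 1)` studies
#' are generated, each reporting the compound and the reference at three
#' doses with a peaked reference dose-response (so the "reference-maximal
#' condition" selection rule is exercised downstream). The raw response is
#'
#'   `raw(i, s, m, study) = exp(x_i . beta_{s,m}) * ref_baseline * noise`
#'
#' with lognormal noise of coefficient of variation `study_noise_cv`
#' (times a per-system factor) applied on the ratio scale: the reference's
#' own records carry the bare baseline, so normalized responses are
#' `exp(x . beta) * noise` and the reference is exactly 1 in every study.
#'
#' @param descriptors descriptor matrix from [generate_chemical_space()].
#' @param truth matching `ground_truth`.
#' @param config the same [generator_config()].
#' @return A data.frame of response records in the documented CSV layout
#'   (`compound_id, study_id, species, setting, presentation, marker, dose,
#'   dose_unit, time, time_unit, value`).
#' @export
generate_response_studies <- function(descriptors, truth, config) {
  stopifnot(inherits(config, "generator_config"), inherits(truth, "ground_truth"))
  if (!truth$reference_compound_id %in% rownames(descriptors))
    stop("reference compound '", truth$reference_compound_id,
         "' missing from descriptor matrix")
  set.seed(config$seed + 1000L)
  ids <- rownames(descriptors)
  ref <- truth$reference_compound_id
  doses <- c(10, 100, 1000)           # ng/mL (or ng/mouse in vivo)
  dose_shape <- c(0.6, 1.0, 0.75)     # peaked at the middle dose
  baseline0 <- c("IL-2" = 200, "IFN-g" = 800, "IL-4" = 400, "IL-13" = 300)  # pg/mL

  rows <- vector("list", 2048); nr <- 0L
  push <- function(df) {
    nr <<- nr + 1L
    if (nr > length(rows)) length(rows) <<- 2L * nr
    rows[[nr]] <<- df
  }

  for (s in config$systems) {
    sp <- sub("/.*", "", s)
    st <- if (grepl("in vivo", s)) "in_vivo" else "in_vitro"
    pr <- if (grepl("cell-cell", s)) "cell_cell" else if (grepl("cell-plate", s)) "cell_plate" else ""
    for (m in config$markers) {
      cl <- cell_label(s, m)
      beta <- truth$coefficients[[cl]]
      cv <- config$study_noise_cv * system_noise_factor[[s]]
      sdlog <- sqrt(log1p(cv^2))
      measured <- stats::runif(length(ids)) < config$measure_prob[[cl]]
      measured[ids == ref] <- FALSE   # reference appears inside every study
      for (i in which(measured)) {
        k <- 1L + stats::rpois(1L, config$n_studies_mean - 1)
        mu <- exp(sum(descriptors[i, ] * beta))
        for (j in seq_len(k)) {
          study <- sprintf("S_%s_%s_%s_%d", gsub("[^a-z]", "", tolower(s)),
                           gsub("[^A-Za-z0-9]", "", m), ids[i], j)
          base <- baseline0[[m]] * stats::rlnorm(1L, 0, 0.4)  # study-level assay scale
          ref_raw <- base * dose_shape
          noise <- if (sdlog > 0) stats::rlnorm(1L, -sdlog^2 / 2, sdlog) else 1
          ana_raw <- mu * noise * ref_raw
          push(data.frame(
            compound_id = c(rep(ref, 3L), rep(ids[i], 3L)),
            study_id = study,
            species = sp, setting = st, presentation = pr,
            marker = m,
            dose = rep(doses, 2L), dose_unit = "ng/mL",
            time = 24, time_unit = "h",
            value = c(ref_raw, ana_raw),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(nr)])
  rownames(out) <- NULL
  out
}

#' Lognormal noise CV that yields a target signal R-squared
#'
#' Given descriptors and a log-scale coefficient vector, returns the
#' `study_noise_cv` for which the expected coefficient of determination of
#' log-response on the descriptors equals `r2`:
#' `sigma^2 = var(X beta) * (1 - r2) / r2`, `cv = sqrt(exp(sigma^2) - 1)`.
#'
#' @param descriptors compound x descriptor matrix.
#' @param beta descriptor-length coefficient vector (log scale).
#' @param r2 target fraction of log-response variance explained.
#' @return A coefficient of variation (fraction).
#' @export
noise_cv_for_r2 <- function(descriptors, beta, r2 = 0.8) {
  stopifnot(r2 > 0, r2 < 1)
  s2 <- stats::var(as.vector(descriptors %*% beta)) * (1 - r2) / r2
  sqrt(expm1(s2))
}

#' Write a small, fully reproducible fixture suite to disk
#'
#' Writes a <= 50 compound synthetic response table, descriptor matrix and
#' ground-truth JSON, plus the packaged measurement-frequency count fixture,
#' and a JSON manifest listing each file with its md5 checksum.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return The manifest, invisibly (list of file, md5).
#' @export
generate_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create fixture directory: ", out_dir)
  cfg <- fixture_config(seed)
  cs <- generate_chemical_space(cfg)
  resp <- generate_response_studies(cs$descriptors, cs$truth, cfg)

  paths <- c(responses = file.path(out_dir, "responses.csv"),
             descriptors = file.path(out_dir, "descriptors.csv"),
             ground_truth = file.path(out_dir, "ground_truth.json"),
             frequency_counts = file.path(out_dir, "frequency_counts.csv"))
  utils::write.csv(resp, paths[["responses"]], row.names = FALSE)
  utils::write.csv(data.frame(compound_id = rownames(cs$descriptors),
                              cs$descriptors, check.names = FALSE),
                   paths[["descriptors"]], row.names = FALSE)
  jsonlite::write_json(list(
    reference_compound_id = cs$truth$reference_compound_id,
    informative_indices = cs$truth$informative_indices,
    informative_names = cs$truth$informative_names,
    beta_base = cs$truth$beta_base,
    coefficients = cs$truth$coefficients
  ), paths[["ground_truth"]], auto_unbox = TRUE, digits = NA)
  utils::write.csv(table1_counts(), paths[["frequency_counts"]], row.names = FALSE)

  manifest <- list(seed = as.integer(seed),
                   files = lapply(stats::setNames(nm = names(paths)), function(k)
                     list(file = basename(paths[[k]]),
                          md5 = unname(tools::md5sum(paths[[k]])))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# 50-compound fixture conditions: dense enough in the four modelled cells
# that every desirability axis is populated
fixture_config <- function(seed = 1L) {
  mp <- default_measure_prob()
  dense <- as.vector(outer(c("mice/in vivo", "mice/in vitro/cell-cell",
                             "human/in vitro/cell-cell"),
                           c("IFN-g", "IL-4"), cell_label))
  mp[dense] <- 0.85
  generator_config(n_compounds = 50, n_descriptors = 30, n_informative = 4,
                   n_constant = 2, study_noise_cv = 0.3,
                   measure_prob = mp, seed = seed)
}
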