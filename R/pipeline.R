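#' Pipeline configuration
#'
#' @param response_file path to the per-study response CSV.
#' @param descriptor_file path to the compound x descriptor CSV (first
#'   column `compound_id`).
#' @param reference_id reference compound id (alpha-GalCer).
#' @param out_dir output directory for artifacts.
#' @param desirability a [desirability_config()].
#' @param p_enter,p_remove stepwise MLR probability-of-F thresholds.
#' @param k_folds cross-validation folds (default 7).
#' @param max_pls_components upper bound for the Q2-driven component rule.
#' @param min_model_rows minimum complete-case rows to fit an axis model.
#' @param pca_components PCA components to export.
#' @param seed integer seed (cross-validation folds).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(response_file, descriptor_file,
                            reference_id = "C001",
                            out_dir = "pipeline_out",
                            desirability = desirability_config(),
                            p_enter = 0.05, p_remove = 0.10,
                            k_folds = 7L, max_pls_components = 5L,
                            min_model_rows = 10L, pca_components = 2L,
                            seed = 1L) {
  for (f in c(response_file, descriptor_file))
    if (!file.exists(f)) stop("input file not found: ", f)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the end-to-end structure-immune pipeline
#'
#' Ingest -> reference normalization -> replicate aggregation and frequency
#' summary -> desirability axes -> chemical space (pruning, PCA, UPGMA) ->
#' test-model variability -> stepwise MLR and PLS models with k-fold Q2 ->
#' ROC at the reference-D cutoff. All tabular artifacts are written as CSV
#' (models as JSON, dendrogram as Newick) under `config$out_dir`; a run
#' report summarizes stage row counts. Identical config and inputs produce
#' byte-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return The run report (list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed,
                 package_version = as.character(utils::packageVersion("inktqsar")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  outfile <- function(name) file.path(config$out_dir, name)

  records <- stage("ingest", read_response_table(config$response_file))
  report$n_records <- nrow(records)

  normalized <- stage("normalize",
                      suppressWarnings(normalize_to_reference(records, config$reference_id)))
  report$n_normalized <- nrow(normalized)

  mat <- stage("aggregate", aggregate_replicates(normalized))
  utils::write.csv(data.frame(compound_id = rownames(mat$values), mat$values,
                              check.names = FALSE),
                   outfile("relative_responses.csv"), row.names = FALSE)
  freq <- stage("frequencies", summarize_frequencies(mat))
  utils::write.csv(as.data.frame(freq), outfile("frequencies.csv"), row.names = FALSE)
  report$n_results <- attr(freq, "grand_total")

  dtab <- stage("desirability",
                suppressWarnings(desirability_profiles(mat, config$desirability)))
  utils::write.csv(as.data.frame(dtab), outfile("desirability.csv"), row.names = FALSE)
  report$axes_present <- vapply(desirability_axes(), function(a)
    sum(!is.na(axis_d_values(dtab, a, drop_na = FALSE))) > 0L, TRUE)

  desc_df <- stage("descriptors", utils::read.csv(config$descriptor_file,
                                                  check.names = FALSE))
  x_raw <- as.matrix(desc_df[, -1L, drop = FALSE])
  rownames(x_raw) <- desc_df[[1L]]
  x <- stage("chemspace", prune_constant_descriptors(x_raw))
  report$n_descriptors_removed <- length(attr(x, "removed"))
  pca <- stage("pca", pca_scores(x, n_components = min(config$pca_components,
                                                       nrow(x) - 1L, ncol(x))))
  utils::write.csv(data.frame(compound_id = rownames(pca$scores), pca$scores,
                              check.names = FALSE),
                   outfile("pca_scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(descriptor = rownames(pca$loadings), pca$loadings,
                              check.names = FALSE),
                   outfile("pca_loadings.csv"), row.names = FALSE)
  hc <- stage("hca", hca_average_linkage(x))
  write_dendrogram_newick(hc, outfile("dendrogram.nwk"))
  utils::write.csv(merge_table(hc), outfile("hca_merges.csv"), row.names = FALSE)

  vr <- stage("variability", tryCatch(variability_report(normalized),
                                      error = function(e) NULL))
  if (!is.null(vr)) {
    utils::write.csv(vr$cells, outfile("variability_cells.csv"), row.names = FALSE)
    if (!is.null(vr$cross_model))
      utils::write.csv(vr$cross_model, outfile("variability_cross_model.csv"),
                       row.names = FALSE)
  }

  models <- list(); rocs <- list()
  for (axis in desirability_axes()) {
    d <- axis_d_values(dtab, axis)
    d <- d[names(d) %in% rownames(x)]
    if (length(d) < config$min_model_rows) {
      warning("axis '", axis, "': only ", length(d),
              " complete rows; model skipped")
      next
    }
    xa <- x[names(d), , drop = FALSE]
    mlr <- stage(paste0("mlr:", axis),
                 suppressWarnings(stepwise_mlr_fit(xa, d, config$p_enter,
                                                   config$p_remove)))
    nc <- stage(paste0("pls:", axis),
                choose_pls_ncomp(xa, d, config$max_pls_components,
                                 k = min(config$k_folds, length(d)),
                                 seed = config$seed))
    pls <- pls_fit(xa, d, nc$n_components)
    q2 <- kfold_q2(xa, d, pls_spec(nc$n_components),
                   k = min(config$k_folds, length(d)), seed = config$seed)$q2
    models[[axis]] <- list(axis = axis, n = length(d),
                           mlr = serialize_model(mlr),
                           pls = c(serialize_model(pls), list(q2 = q2)))

    ref_d <- if (config$reference_id %in% names(d)) d[[config$reference_id]] else
      stats::median(d)
    labels <- classify_strength(d, ref_d)
    fitted <- predict_desirability(pls, xa, clip = FALSE)
    if (length(unique(labels)) == 2L) {
      roc <- roc_auc(fitted[names(labels)], labels)
      rocs[[axis]] <- roc
      utils::write.csv(data.frame(threshold = roc$thresholds, tpr = roc$tpr,
                                  fpr = roc$fpr),
                       outfile(paste0("roc_", gsub("[^A-Za-z0-9]+", "_", axis), ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(models, outfile("models.json"), auto_unbox = TRUE,
                       digits = NA)
  report$models <- lapply(models, function(m)
    list(n = m$n, mlr_r2 = m$mlr$r2, mlr_terms = length(m$mlr$selected),
         pls_r2 = m$pls$r2, pls_q2 = m$pls$q2,
         pls_components = m$pls$n_components))
  report$auc <- lapply(rocs, function(r) r$auc)

  writeLines(format_run_report(report), outfile("run_report.txt"))
  invisible(report)
}

serialize_model <- function(model) {
  if (inherits(model, "mlr_model")) {
    list(type = "mlr", selected = model$selected,
         coefficients = as.list(model$coefficients),
         intercept = model$intercept, r2 = model$r2, n = model$n,
         trace = model$trace)
  } else {
    list(type = "pls", n_components = model$n_components,
         coefficients = as.list(model$coefficients),
         intercept = model$intercept, r2 = model$r2, n = model$n)
  }
}

format_run_report <- function(report) {
  lines <- c("Structure-immune pipeline run report",
             sprintf("package version: %s", report$package_version),
             sprintf("seed: %d", report$seed),
             sprintf("raw records: %d", report$n_records),
             sprintf("normalized per-study values: %d", report$n_normalized),
             sprintf("aggregated results: %d", report$n_results),
             sprintf("constant descriptors removed: %d", report$n_descriptors_removed),
             sprintf("axes populated: %s",
                     paste(names(report$axes_present)[report$axes_present],
                           collapse = ", ")))
  for (axis in names(report$models)) {
    m <- report$models[[axis]]
    lines <- c(lines, sprintf(
      "%s: n = %d | MLR R2 = %.3f (%d terms) | PLS R2 = %.3f, Q2 = %.3f (%d comp)%s",
      axis, m$n, m$mlr_r2, m$mlr_terms, m$pls_r2, m$pls_q2, m$pls_components,
      if (!is.null(report$auc[[axis]]))
        sprintf(" | AUC = %.3f", report$auc[[axis]]) else ""))
  }
  lines
}
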