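#' Classify analogues as strong or weak polarizers at the reference cutoff
#'
#' Strong means a D-value strictly higher than the reference compound's
#' (alpha-GalCer's) D on the same axis; the reference itself is weak.
#' Missing D-values are excluded (with a warning when nothing is labelled).
#'
#' @param d_values named numeric vector of D-values.
#' @param reference_d the reference compound's D-value on the same axis.
#' @return Named logical vector (`TRUE` = strong) over the non-missing
#'   compounds.
#' @export
classify_strength <- function(d_values, reference_d) {
  stopifnot(length(reference_d) == 1L, reference_d >= 0.1, reference_d <= 0.9)
  lab <- d_values[!is.na(d_values)] > reference_d
  if (length(lab) == 0L) warning("no compound has a D-value; empty label set")
  lab
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC is the probability that a random strong compound scores above a
#' random weak one, with ties counted half:
#' `AUC = (sum of positive mid-ranks - n_pos (n_pos + 1) / 2) / (n_pos n_neg)`.
#' The curve is generated by sweeping the decision threshold over the unique
#' scores (plus sentinels), so it starts at (0, 0) and ends at (1, 1).
#'
#' @param scores numeric predictions (e.g. fitted D-values).
#' @param labels logical (or 0/1) vector, `TRUE` = strong/positive.
#' @return An `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`, `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("need at least one positive and one negative label")
  r <- rank(scores)  # mid-ranks
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores[labels] >= t) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores[!labels] >= t) / n_neg, 0)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d strong vs %d weak)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare a fitted model's selected descriptors against generator truth
#'
#' For synthetic benchmarks with known informative descriptors: reports the
#' selection confusion (sensitivity over informative descriptors, count of
#' false inclusions), the sign agreement of estimated vs true coefficients
#' on the correctly selected set, and the Spearman correlation between
#' estimated and true coefficients over all descriptors (unselected
#' descriptors count as zero).
#'
#' @param truth a `ground_truth` object from [generate_chemical_space()].
#' @param model a fitted `mlr_model` or `pls_model`.
#' @param cell the `(test-system, marker)` cell label whose true coefficient
#'   vector the model targets; defaults to the IFN-g response of the
#'   mice in-vivo system.
#' @return list `(n_informative, n_selected, true_positives, sensitivity,
#'   false_inclusions, sign_agreement, coef_rank_correlation)`.
#' @export
parameter_recovery_report <- function(truth, model,
                                      cell = cell_label("mice/in vivo", "IFN-g")) {
  stopifnot(inherits(truth, "ground_truth"))
  beta <- truth$coefficients[[cell]]
  if (is.null(beta)) stop("unknown cell in ground truth: ", cell)
  names(beta) <- truth$descriptor_names
  info <- truth$informative_names
  model_names <- if (inherits(model, "mlr_model")) model$selected else
    names(model$coefficients)
  if (length(model_names) && !all(model_names %in% truth$descriptor_names))
    stop("model and ground truth use different descriptor vocabularies: ",
         paste(setdiff(model_names, truth$descriptor_names), collapse = ", "))

  est <- stats::setNames(numeric(length(beta)), names(beta))
  if (inherits(model, "mlr_model")) {
    selected <- model$selected
    est[selected] <- model$coefficients[selected]
  } else {
    est[names(model$coefficients)] <- model$coefficients
    # for PLS "selected" means the descriptors with non-negligible weight
    selected <- names(model$coefficients)[abs(model$coefficients_scaled) >
                             0.1 * max(abs(model$coefficients_scaled))]
  }
  tp <- intersect(selected, info)
  fi <- setdiff(selected, info)
  sign_ok <- if (length(tp)) mean(sign(est[tp]) == sign(beta[tp])) else NA_real_
  rc <- suppressWarnings(stats::cor(rank(est), rank(beta)))
  list(n_informative = length(info), n_selected = length(selected),
       true_positives = length(tp),
       sensitivity = length(tp) / length(info),
       false_inclusions = length(fi),
       sign_agreement = sign_ok,
       coef_rank_correlation = rc)
}
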