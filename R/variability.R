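#' Per-compound intra-variability (relative standard deviation)
#'
#' The intrinsic precision of a test-model: for every compound with the same
#' (test-system, marker) response measured in more than one study,
#' `RSD = 100 * sd / mean` of the per-study normalized responses (sample,
#' n-1, standard deviation). Compounds with fewer than two replicates, or a
#' zero mean, are excluded.
#'
#' @param normalized per-study normalized records
#'   (`compound_id, test_system, marker, normalized`), typically restricted
#'   to one cell; RSDs are computed per (compound, cell).
#' @return data.frame `(compound_id, test_system, marker, n, rsd)`.
#' @export
intra_rsd <- function(normalized) {
  key <- paste(normalized$compound_id, normalized$test_system,
               normalized$marker, sep = "\r")
  out <- lapply(split(normalized, key), function(grp) {
    if (nrow(grp) < 2L) return(NULL)
    m <- mean(grp$normalized)
    if (m == 0) {
      warning("zero mean response for compound ", grp$compound_id[1L],
              "; excluded from RSD")
      return(NULL)
    }
    data.frame(compound_id = grp$compound_id[1L],
               test_system = grp$test_system[1L],
               marker = grp$marker[1L],
               n = nrow(grp),
               rsd = 100 * stats::sd(grp$normalized) / m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) out <- data.frame(compound_id = character(), test_system = character(),
                                      marker = character(), n = integer(), rsd = numeric())
  rownames(out) <- NULL
  out
}

#' Inter-variability corrected for intrinsic intra-variability
#'
#' The discriminating power of a test-model: the spread of per-compound mean
#' responses, with the replication noise subtracted on the variance scale
#' and floored at zero:
#' `100 * sqrt(max(0, var(compound means) - mean(intra variances))) / grand mean`.
#'
#' @param compound_means per-compound aggregated normalized responses for
#'   one (test-system, marker) cell (>= 3 values).
#' @param intra_variances per-compound intra-study variances on the same
#'   scale (from compounds with >= 2 replicates); may be empty, in which
#'   case no correction is applied.
#' @return Corrected inter-RSD in percent.
#' @export
inter_rsd_corrected <- function(compound_means, intra_variances = numeric()) {
  compound_means <- compound_means[!is.na(compound_means)]
  if (length(compound_means) < 3L) stop("need >= 3 compounds for inter-variability")
  gm <- mean(compound_means)
  if (gm == 0) stop("grand mean response is zero")
  s2_between <- stats::var(compound_means)
  s2_intra <- if (length(intra_variances)) mean(intra_variances, na.rm = TRUE) else 0
  100 * sqrt(max(0, s2_between - s2_intra)) / gm
}

#' Kruskal-Wallis rank test across test-models
#'
#' Wraps [stats::kruskal.test()] (rank-based H with tie correction,
#' chi-square p with groups - 1 degrees of freedom). The degenerate case of
#' all values identical across all groups returns H = 0, p = 1.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list `(H, df, p_value)`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) stop("all groups must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p_value = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Spearman rank correlation between two test-models
#'
#' Pearson correlation of mid-ranks, with a two-sided p-value from the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs).
#' @return list `(rho, n, p_value)`; `rho` is `NA` when either variable has
#'   zero rank variance.
#' @export
spearman_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, n = n, p_value = NA_real_))
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, n = n, p_value = p)
}

#' Test-model variability and agreement report
#'
#' Per (test-system, marker) cell: per-compound intra RSDs and their median,
#' and the corrected inter-RSD (discriminating power). Across test-models:
#' Kruskal-Wallis comparison of the intra-RSD distributions per marker, and
#' pairwise Spearman correlations of compound responses between models
#' (complete cases only).
#'
#' @param normalized per-study normalized records
#'   (from [normalize_to_reference()]).
#' @param systems test-systems to compare (default the three main ones:
#'   both cell-cell systems and mice in vivo).
#' @param markers markers to compare (default IFN-g and IL-4).
#' @param min_pairs minimum complete pairs for a cross-model correlation.
#' @return A `variability_report` list: `intra` (per-compound RSDs),
#'   `cells` (per-cell medians and corrected inter-RSDs),
#'   `kruskal` (per-marker H/p across systems),
#'   `cross_model` (pairwise Spearman rho/p).
#' @export
variability_report <- function(normalized,
                               systems = c("mice/in vivo",
                                           "mice/in vitro/cell-cell",
                                           "human/in vitro/cell-cell"),
                               markers = c("IFN-g", "IL-4"),
                               min_pairs = 3L) {
  normalized <- normalized[normalized$test_system %in% systems &
                             normalized$marker %in% markers, , drop = FALSE]
  if (nrow(normalized) == 0L) stop("no records in the requested systems/markers")
  intra <- intra_rsd(normalized)

  cells <- list()
  for (s in systems) for (m in markers) {
    sel <- normalized$test_system == s & normalized$marker == m
    if (!any(sel)) next
    means <- tapply(normalized$normalized[sel], normalized$compound_id[sel], mean)
    vars <- tapply(normalized$normalized[sel], normalized$compound_id[sel],
                   function(v) if (length(v) >= 2L) stats::var(v) else NA_real_)
    vars <- vars[!is.na(vars)]
    irs <- intra$rsd[intra$test_system == s & intra$marker == m]
    inter <- if (length(means) >= 3L && mean(means) > 0)
      inter_rsd_corrected(as.numeric(means), as.numeric(vars)) else NA_real_
    cells[[cell_label(s, m)]] <- data.frame(
      test_system = s, marker = m,
      n_compounds = length(means),
      n_replicated = length(irs),
      median_intra_rsd = if (length(irs)) stats::median(irs) else NA_real_,
      inter_rsd_corrected = inter,
      stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL

  kr <- lapply(stats::setNames(nm = markers), function(m) {
    gl <- lapply(systems, function(s)
      intra$rsd[intra$test_system == s & intra$marker == m])
    gl <- gl[lengths(gl) > 0L]
    if (length(gl) < 2L) return(NULL)
    kruskal_wallis(gl)
  })
  kr <- kr[!vapply(kr, is.null, TRUE)]

  cross <- list()
  pairs <- utils::combn(systems, 2L, simplify = FALSE)
  for (m in markers) for (pp in pairs) {
    m1 <- tapply(normalized$normalized[normalized$test_system == pp[1L] &
                                         normalized$marker == m],
                 normalized$compound_id[normalized$test_system == pp[1L] &
                                          normalized$marker == m], mean)
    m2 <- tapply(normalized$normalized[normalized$test_system == pp[2L] &
                                         normalized$marker == m],
                 normalized$compound_id[normalized$test_system == pp[2L] &
                                          normalized$marker == m], mean)
    common <- intersect(names(m1), names(m2))
    if (length(common) < min_pairs) next
    sc <- spearman_correlation(as.numeric(m1[common]), as.numeric(m2[common]))
    cross[[paste(m, pp[1L], pp[2L], sep = " | ")]] <-
      data.frame(marker = m, system_a = pp[1L], system_b = pp[2L],
                 n = sc$n, rho = sc$rho, p_value = sc$p_value,
                 stringsAsFactors = FALSE)
  }
  cross <- if (length(cross)) do.call(rbind, cross) else NULL
  if (!is.null(cross)) rownames(cross) <- NULL

  structure(list(intra = intra, cells = cells, kruskal = kr,
                 cross_model = cross),
            class = "variability_report")
}

#' @export
print.variability_report <- function(x, ...) {
  cat("Test-model variability report\n")
  print(x$cells)
  for (m in names(x$kruskal))
    cat(sprintf("Kruskal-Wallis intra-RSD, %s: H = %.3f, p = %.4f\n",
                m, x$kruskal[[m]]$H, x$kruskal[[m]]$p_value))
  if (!is.null(x$cross_model)) {
    cat("Cross-model Spearman correlations:\n")
    print(x$cross_model)
  }
  invisible(x)
}
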