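#' Derringer d-transform of a normalized response
#'
#' Linear one-sided desirability on the 0.1-0.9 scale. For a larger-better
#' response, `d = 0.1 + 0.8 * (y - Y_lo) / (Y_hi - Y_lo)` clipped to
#' [0.1, 0.9]; smaller-better is the mirror image (y = Y_lo maps to 0.9).
#' Values beyond the anchors clip rather than error, so compounds exceeding
#' the historical maximum response remain scoreable.
#'
#' @param y normalized response(s), >= 0.
#' @param anchor numeric `(Y_lo, Y_hi)` on the normalized-response scale,
#'   `Y_hi > Y_lo`.
#' @param direction `"larger"` or `"smaller"` (which end is desirable).
#' @return d-value(s) in [0.1, 0.9]; `NA` propagates.
#' @export
d_transform <- function(y, anchor, direction = c("larger", "smaller")) {
  direction <- match.arg(direction)
  if (length(anchor) != 2L || !all(is.finite(anchor)) || anchor[2L] <= anchor[1L])
    stop("anchor must be (Y_lo, Y_hi) with Y_hi > Y_lo")
  d <- 0.1 + 0.8 * (y - anchor[1L]) / (anchor[2L] - anchor[1L])
  if (direction == "smaller") d <- 1 - d
  pmin(0.9, pmax(0.1, d))
}

#' Overall desirability: geometric mean of component d-values
#'
#' A compound whose component desirabilities are 0.1 and 0.9 (for instance
#' both IFN-g and IL-4 very high) scores `sqrt(0.1 * 0.9) = 0.3`, reflecting
#' that an unpolarized strong response is not clinically interesting.
#'
#' @param d numeric vector of d-values in [0.1, 0.9].
#' @return The D-value, in [0.1, 0.9].
#' @export
overall_desirability <- function(d) {
  if (length(d) == 0L) stop("no component d-values")
  if (any(is.na(d)) || any(d <= 0)) stop("component d-values must be positive and non-missing")
  if (any(d < 0.1 - 1e-12 | d > 0.9 + 1e-12))
    stop("component d-values must lie in [0.1, 0.9]")
  geometric_mean(d)
}

#' Desirability configuration
#'
#' @param include_il13 add IL-13 (alongside IL-4) as a Th2-cytokine
#'   component of the Th2/Th1 axes; default `FALSE` (the axes are defined on
#'   IFN-g and IL-4 only).
#' @param anchors optional named list of `(Y_lo, Y_hi)` per
#'   `"<group>|<marker>"` with group `"in vivo"` or `"in vitro"`; anchors
#'   not supplied are derived from the data as `(0, max observed)`.
#' @return A `desirability_config` list.
#' @export
desirability_config <- function(include_il13 = FALSE, anchors = NULL) {
  structure(list(include_il13 = include_il13, anchors = anchors,
                 d_min = 0.1, d_max = 0.9),
            class = "desirability_config")
}

# pooled per-compound responses for an axis group:
# "in vivo" = mice/in vivo; "in vitro" = mean of the human and mice
# cell-cell systems (plate-bound systems excluded from the axes)
pooled_group_response <- function(mat, group, marker) {
  systems <- if (group == "in vivo") "mice/in vivo" else
    c("mice/in vitro/cell-cell", "human/in vitro/cell-cell")
  cols <- intersect(cell_label(systems, marker), colnames(mat$values))
  if (length(cols) == 0L) return(rep(NA_real_, nrow(mat$values)))
  rowMeans(mat$values[, cols, drop = FALSE], na.rm = TRUE)
}

#' Compute the four Th1/Th2 desirability axes
#'
#' For each compound, the Th1 axis combines a larger-better IFN-g component
#' with a smaller-better IL-4 component (Th2 axes are the reverse), on the
#' in-vivo responses and on the pooled in-vitro cell-cell responses
#' (human and mice averaged per compound when both are present). Component
#' d-values use anchors `(0, Y_max)` where `Y_max` is the maximum observed
#' pooled response for the group and marker, unless overridden in the
#' config. D is the geometric mean of the components and is missing where
#' any component response is missing.
#'
#' @param mat a `relative_response_matrix`.
#' @param config a [desirability_config()].
#' @return A `desirability_table` data.frame with one row per
#'   (compound, axis): component d-values and the overall `D`; anchors used
#'   are attached as an attribute.
#' @export
desirability_profiles <- function(mat, config = desirability_config()) {
  stopifnot(inherits(mat, "relative_response_matrix"))
  groups <- c("in vivo", "in vitro")
  mks <- c("IFN-g", "IL-4", if (config$include_il13) "IL-13")
  resp <- list(); anchors <- list()
  for (g in groups) for (m in mks) {
    key <- paste(g, m, sep = "|")
    y <- pooled_group_response(mat, g, m)
    y[is.nan(y)] <- NA_real_
    resp[[key]] <- y
    a <- config$anchors[[key]]
    if (is.null(a)) {
      hi <- suppressWarnings(max(y, na.rm = TRUE))
      a <- c(0, if (is.finite(hi) && hi > 0) hi else 1)
    }
    anchors[[key]] <- a
  }

  axes <- list()
  for (g in groups) for (pol in c("Th1", "Th2")) {
    ifng_dir <- if (pol == "Th1") "larger" else "smaller"
    il4_dir <- if (pol == "Th1") "smaller" else "larger"
    d_ifng <- d_transform(resp[[paste(g, "IFN-g", sep = "|")]],
                          anchors[[paste(g, "IFN-g", sep = "|")]], ifng_dir)
    d_il4 <- d_transform(resp[[paste(g, "IL-4", sep = "|")]],
                         anchors[[paste(g, "IL-4", sep = "|")]], il4_dir)
    comp <- cbind(d_IFNg = d_ifng, d_IL4 = d_il4)
    if (config$include_il13) {
      d13 <- d_transform(resp[[paste(g, "IL-13", sep = "|")]],
                         anchors[[paste(g, "IL-13", sep = "|")]], il4_dir)
      comp <- cbind(comp, d_IL13 = d13)
    }
    D <- apply(comp, 1L, function(d) if (any(is.na(d))) NA_real_ else geometric_mean(d))
    axis_name <- paste(pol, g)
    if (all(is.na(D)))
      warning("axis '", axis_name, "' has no compound with complete components")
    axes[[axis_name]] <- data.frame(compound_id = rownames(mat$values),
                                    axis = axis_name, comp, D = D,
                                    stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, axes)
  rownames(out) <- NULL
  structure(out, class = c("desirability_table", "data.frame"),
            anchors = anchors)
}

#' Extract one axis of a desirability table as a named D vector
#'
#' @param dtab a `desirability_table`.
#' @param axis axis name, e.g. `"Th1 in vivo"`.
#' @param drop_na drop compounds without a D-value (default `TRUE`).
#' @return Named numeric vector of D-values.
#' @export
axis_d_values <- function(dtab, axis, drop_na = TRUE) {
  r <- dtab[dtab$axis == axis, , drop = FALSE]
  if (nrow(r) == 0L) stop("unknown axis: ", axis)
  d <- stats::setNames(r$D, r$compound_id)
  if (drop_na) d <- d[!is.na(d)]
  d
}

#' Names of the four desirability axes
#' @return Character vector.
#' @export
desirability_axes <- function() {
  c("Th1 in vivo", "Th2 in vivo", "Th1 in vitro", "Th2 in vitro")
}
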