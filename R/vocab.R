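#' Closed vocabularies: test-systems and cytokine markers
#'
#' The dataset grid is five assay contexts ("test-systems": species crossed
#' with in-vivo/in-vitro and, for in-vitro, cell-cell vs plate-bound CD1d
#' presentation) by four cytokine markers, so each compound can contribute at
#' most 20 aggregated responses.
#'
#' @return Character vector of canonical labels.
#' @export
test_systems <- function() {
  c("mice/in vivo",
    "mice/in vitro/cell-cell",
    "mice/in vitro/cell-plate",
    "human/in vitro/cell-cell",
    "human/in vitro/cell-plate")
}

#' @rdname test_systems
#' @export
markers <- function() {
  c("IL-2", "IFN-g", "IL-4", "IL-13")
}

#' Normalize a marker label to the canonical vocabulary
#'
#' Case-insensitive; tolerates missing hyphens and common spellings of
#' interferon-gamma ("IFN-gamma", "IFNg", the Greek letter).
#'
#' @param x character vector of marker labels.
#' @return Canonical labels; `NA` where the label is not recognized.
#' @export
normalize_marker <- function(x) {
  key <- tolower(enc2utf8(as.character(x)))
  key <- gsub("\u03b3", "g", key)  # Greek gamma
  key <- gsub("[^a-z0-9]+", "", key)
  lut <- c(il2 = "IL-2",
           ifng = "IFN-g", ifngamma = "IFN-g", interferongamma = "IFN-g",
           il4 = "IL-4", il13 = "IL-13")
  unname(lut[key])
}

#' Normalize species/setting/presentation fields into a test-system label
#'
#' @param species "mice"/"mouse"/"murine" or "human".
#' @param setting "in vivo" or "in vitro" (any separator).
#' @param presentation "cell-cell" or "cell-plate"; ignored for in vivo,
#'   where it may be empty or `NA`.
#' @return Canonical test-system labels; `NA` where fields do not resolve.
#' @export
normalize_test_system <- function(species, setting, presentation) {
  sp <- tolower(trimws(as.character(species)))
  sp <- ifelse(sp %in% c("mice", "mouse", "murine"), "mice",
               ifelse(sp %in% c("human", "humans"), "human", NA))
  st <- gsub("[^a-z]", "", tolower(as.character(setting)))
  st <- ifelse(st == "invivo", "in vivo", ifelse(st == "invitro", "in vitro", NA))
  pr <- gsub("[^a-z]", "", tolower(as.character(presentation)))
  pr <- ifelse(pr %in% c("cellcell", "cc"), "cell-cell",
               ifelse(pr %in% c("cellplate", "cp", "platebound"), "cell-plate", NA))
  out <- ifelse(st == "in vivo", paste(sp, st, sep = "/"),
                paste(sp, st, pr, sep = "/"))
  out[!(out %in% test_systems()) | is.na(sp) | is.na(st)] <- NA
  out
}

# label of one (test-system, marker) cell, used as a matrix column name
cell_label <- function(test_system, marker) paste(test_system, marker, sep = "|")

split_cell_label <- function(label) {
  parts <- strsplit(label, "|", fixed = TRUE)
  data.frame(test_system = vapply(parts, `[`, "", 1L),
             marker = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Geometric mean
#'
#' @param x positive numeric values.
#' @return `(prod(x))^(1/n)`, computed on the log scale.
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0L) stop("geometric mean of an empty set is undefined")
  if (any(!is.finite(x)) || any(x <= 0)) stop("geometric mean requires finite positive values")
  exp(mean(log(x)))
}
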