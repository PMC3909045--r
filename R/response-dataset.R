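#' Read a per-study cytokine response table
#'
#' Expected header: `compound_id, study_id, species, setting, presentation,
#' marker, dose, dose_unit, time, time_unit, value`. Marker and test-system
#' vocabulary is normalized case-insensitively; rows that do not resolve to
#' the closed vocabularies, or whose value is missing/non-numeric/negative,
#' are rejected with their line numbers.
#'
#' @param file path to a delimited text file.
#' @param sep field separator (default comma).
#' @return A data.frame of response records with canonical `test_system`
#'   and `marker` columns.
#' @export
read_response_table <- function(file, sep = ",") {
  if (!file.exists(file)) stop("response table not found: ", file)
  raw <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("compound_id", "study_id", "species", "setting", "presentation",
              "marker", "dose", "dose_unit", "time", "time_unit", "value")
  miss <- setdiff(needed, names(raw))
  if (length(miss)) stop("response table missing columns: ", paste(miss, collapse = ", "))
  validate_response_records(raw)
}

# shared validation for file input and in-memory data.frames;
# line numbers refer to data rows (header = line 1)
validate_response_records <- function(raw) {
  n <- nrow(raw)
  if (n == 0L) stop("empty response table")
  ts <- normalize_test_system(raw$species, raw$setting, raw$presentation)
  mk <- normalize_marker(raw$marker)
  val <- suppressWarnings(as.numeric(raw$value))
  bad_ts <- which(is.na(ts))
  bad_mk <- which(is.na(mk))
  bad_val <- which(is.na(val) | val < 0)
  if (length(c(bad_ts, bad_mk, bad_val))) {
    msg <- c(
      if (length(bad_ts)) paste0("unknown test-system at data line(s) ",
                                 paste(bad_ts + 1L, collapse = ", ")),
      if (length(bad_mk)) paste0("unknown marker at data line(s) ",
                                 paste(bad_mk + 1L, collapse = ", ")),
      if (length(bad_val)) paste0("missing/non-numeric/negative value at data line(s) ",
                                  paste(bad_val + 1L, collapse = ", ")))
    stop(paste(msg, collapse = "; "))
  }
  data.frame(compound_id = as.character(raw$compound_id),
             study_id = as.character(raw$study_id),
             test_system = ts,
             marker = mk,
             dose = suppressWarnings(as.numeric(raw$dose)),
             dose_unit = as.character(raw$dose_unit),
             time = suppressWarnings(as.numeric(raw$time)),
             time_unit = as.character(raw$time_unit),
             value = val,
             stringsAsFactors = FALSE)
}

# coerce generator output (which already has canonical species/setting/
# presentation fields) into validated records
as_response_records <- function(df) {
  if (!is.null(df$test_system) && !is.null(df$marker) && !is.null(df$value) &&
      is.numeric(df$value)) return(df)
  validate_response_records(df)
}

#' Select the reference-maximal (dose, time) condition
#'
#' Within one study and one (test-system, marker) cell, returns the dose and
#' time at which the reference compound's raw response is maximal. When
#' several analogue conditions were reported in a study, only the condition
#' at which the reference response peaks is retained downstream. Ties are
#' broken toward the lowest dose, then the earliest time.
#'
#' @param records validated response records (one study, one cell, or more —
#'   filtering is applied internally).
#' @param test_system,marker the cell.
#' @param study_id the study.
#' @param reference_id reference compound id.
#' @return A list `(dose, time)`, or `NULL` (with a warning) if the
#'   reference is absent from the study/cell.
#' @export
select_reference_condition <- function(records, test_system, marker, study_id,
                                       reference_id) {
  r <- records[records$test_system == test_system & records$marker == marker &
                 records$study_id == study_id &
                 records$compound_id == reference_id, , drop = FALSE]
  if (nrow(r) == 0L) {
    warning("reference '", reference_id, "' absent from study ", study_id,
            " cell ", cell_label(test_system, marker), "; study skipped")
    return(NULL)
  }
  r <- r[order(-r$value, r$dose, r$time), , drop = FALSE]
  list(dose = r$dose[1L], time = r$time[1L])
}

#' Normalize raw responses to the reference compound, per study
#'
#' For every (study, test-system, marker) cell: pick the condition at which
#' the reference peaks ([select_reference_condition()]), keep records at that
#' condition, and divide each analogue's raw value by the reference's raw
#' value there. Studies without the reference are skipped with a warning;
#' cells where the reference response is zero are dropped with a warning.
#'
#' @param records validated response records.
#' @param reference_id reference compound id (alpha-GalCer).
#' @return A data.frame `(compound_id, study_id, test_system, marker,
#'   normalized)`; the reference maps to 1 in every retained study.
#' @export
normalize_to_reference <- function(records, reference_id) {
  records <- as_response_records(records)
  key <- paste(records$study_id, records$test_system, records$marker, sep = "\r")
  out <- lapply(split(records, key), function(grp) {
    ref <- grp[grp$compound_id == reference_id, , drop = FALSE]
    if (nrow(ref) == 0L) {
      warning("reference '", reference_id, "' absent from study ",
              grp$study_id[1L], " cell ",
              cell_label(grp$test_system[1L], grp$marker[1L]), "; study skipped")
      return(NULL)
    }
    ref <- ref[order(-ref$value, ref$dose, ref$time), , drop = FALSE]
    d0 <- ref$dose[1L]; t0 <- ref$time[1L]; ref_val <- ref$value[1L]
    if (ref_val == 0) {
      warning("reference response is zero in study ", grp$study_id[1L],
              " cell ", cell_label(grp$test_system[1L], grp$marker[1L]),
              "; cell dropped")
      return(NULL)
    }
    sel <- grp[grp$dose == d0 & grp$time == t0, , drop = FALSE]
    data.frame(compound_id = sel$compound_id,
               study_id = sel$study_id,
               test_system = sel$test_system,
               marker = sel$marker,
               normalized = sel$value / ref_val,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out) || nrow(out) == 0L) stop("no study retained after normalization")
  rownames(out) <- NULL
  out
}

#' Average per-study normalized responses into one result per cell
#'
#' One compound evaluated by several research groups in the same
#' (test-system, marker) cell contributes the unweighted arithmetic mean of
#' its normalized responses; the replicate count is kept alongside.
#'
#' @param normalized output of [normalize_to_reference()].
#' @return A `relative_response_matrix`: list with `values` (compound x cell
#'   matrix, `NA` where unmeasured), `n_sources` (integer matrix), and
#'   `cells` (data.frame mapping columns to test-system/marker).
#' @export
aggregate_replicates <- function(normalized) {
  stopifnot(nrow(normalized) >= 1L)
  cells <- unique(cell_label(normalized$test_system, normalized$marker))
  cells <- cells[order(match(split_cell_label(cells)$test_system, test_systems()),
                       match(split_cell_label(cells)$marker, markers()))]
  compounds <- sort(unique(normalized$compound_id))
  vals <- matrix(NA_real_, length(compounds), length(cells),
                 dimnames = list(compounds, cells))
  ns <- matrix(0L, length(compounds), length(cells),
               dimnames = list(compounds, cells))
  lab <- cell_label(normalized$test_system, normalized$marker)
  agg <- stats::aggregate(normalized$normalized,
                          by = list(compound = normalized$compound_id, cell = lab),
                          FUN = mean)
  cnt <- stats::aggregate(normalized$normalized,
                          by = list(compound = normalized$compound_id, cell = lab),
                          FUN = length)
  vals[cbind(agg$compound, agg$cell)] <- agg$x
  ns[cbind(cnt$compound, cnt$cell)] <- cnt$x
  structure(list(values = vals, n_sources = ns,
                 cells = split_cell_label(cells)),
            class = "relative_response_matrix")
}

#' @export
print.relative_response_matrix <- function(x, ...) {
  cat("Relative response matrix:", nrow(x$values), "compounds x",
      ncol(x$values), "(test-system, marker) cells;",
      sum(!is.na(x$values)), "aggregated results\n")
  invisible(x)
}

#' Summarize dataset composition per (test-system, marker) cell
#'
#' Counts one aggregated result per non-missing (compound, cell) and reports
#' each cell's percentage of the grand total (two decimals), the published
#' presentation of dataset composition.
#'
#' @param x a `relative_response_matrix`, a normalized-records data.frame,
#'   or a counts data.frame `(test_system, marker, count)`.
#' @return A `frequency_table` data.frame `(test_system, marker, count,
#'   percent)` with a `grand_total` attribute.
#' @export
summarize_frequencies <- function(x) {
  if (inherits(x, "relative_response_matrix")) {
    counts <- data.frame(split_cell_label(colnames(x$values)),
                         count = colSums(!is.na(x$values)))
  } else if (is.data.frame(x) && all(c("test_system", "marker", "count") %in% names(x))) {
    counts <- x[, c("test_system", "marker", "count")]
  } else if (is.data.frame(x) && all(c("test_system", "marker", "compound_id") %in% names(x))) {
    u <- unique(x[, c("compound_id", "test_system", "marker")])
    tab <- table(cell_label(u$test_system, u$marker))
    counts <- data.frame(split_cell_label(names(tab)), count = as.integer(tab))
  } else stop("cannot summarize frequencies from this input")
  if (nrow(counts) == 0L || sum(counts$count) == 0) stop("no results to summarize")
  total <- sum(counts$count)
  counts$percent <- round(100 * counts$count / total, 2L)
  counts <- counts[order(match(counts$test_system, test_systems()),
                         match(counts$marker, markers())), ]
  rownames(counts) <- NULL
  structure(counts, class = c("frequency_table", "data.frame"),
            grand_total = total)
}

#' Aggregate a frequency table over test-systems
#'
#' @param freq a `frequency_table`.
#' @return A data.frame of per-test-system counts and percentages (two
#'   decimals) of the same grand total.
#' @export
system_shares <- function(freq) {
  stopifnot(inherits(freq, "frequency_table"))
  total <- attr(freq, "grand_total")
  agg <- stats::aggregate(count ~ test_system, data = as.data.frame(freq), FUN = sum)
  agg$percent <- round(100 * agg$count / total, 2L)
  agg[order(match(agg$test_system, test_systems())), ]
}

#' The published measurement-frequency counts
#'
#' Per-cell counts of aggregated literature results for the 333-analogue
#' dataset (grand total 851), shipped as a plain-text fixture.
#'
#' @return A data.frame `(test_system, marker, count)`.
#' @export
table1_counts <- function() {
  f <- system.file("extdata", "table1_counts.csv", package = "inktqsar")
  if (f == "") f <- file.path("inst", "extdata", "table1_counts.csv")
  utils::read.csv(f, stringsAsFactors = FALSE)
}
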