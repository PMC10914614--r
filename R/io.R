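# IO layer: canonical TSV dialects for intensity matrices, annotation
# tables and time-course count tables. UTF-8, tab-separated, "." decimal,
# mandatory header. Empty or "NA" intensity cells mean "not detected" and
# are parsed as 0 (MaxQuant-style absence); a warning reports how many.

#' Reference-complex controlled vocabulary
#'
#' Labels a protein may carry in an annotation table: small (30S) and large
#' (50S) ribosomal subunit, RNA polymerase, some other annotated complex, or
#' none.
#'
#' @return Character vector of allowed `reference_complex` terms.
#' @export
reference_complex_vocabulary <- function() {
  c("30S", "50S", "RNAP", "other", "none")
}

#' Construct and validate an intensity matrix
#'
#' An intensity matrix holds raw (iBAQ-like) protein intensities across 20
#' gradient fractions (`F01`..`F20`) plus the pellet (`P`), one designated
#' spike-in row, and a per-protein organism label.
#'
#' @param values Numeric matrix, proteins x 21 columns (`F01`..`F20`, `P`),
#'   non-negative and finite, with rownames = protein ids.
#' @param organism Character vector, one of `"host"`, `"phage"`,
#'   `"spike_in"` per protein.
#' @param spike_in_id Protein id of the spike-in row; that row must be
#'   strictly positive in all 21 columns.
#' @return An object of class `"intensity_matrix"`: a list with elements
#'   `values`, `organism` (named), `spike_in_id`.
#' @export
intensity_matrix <- function(values, organism, spike_in_id) {
  if (!is.matrix(values) || !is.numeric(values))
    gs_format_error("'values' must be a numeric matrix")
  if (ncol(values) != 21L)
    gs_format_error("intensity matrix must have exactly 21 value columns (F01..F20, P)")
  colnames(values) <- value_columns()
  ids <- rownames(values)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    gs_format_error("all rows must carry a protein_id (rownames)")
  if (anyDuplicated(ids))
    gs_integrity_error(sprintf("duplicate protein_id: %s",
                               ids[duplicated(ids)][1L]))
  if (any(!is.finite(values)))
    gs_format_error("intensity values must be finite")
  if (any(values < 0))
    gs_format_error("intensity values must be non-negative")
  if (length(organism) != nrow(values))
    gs_format_error("'organism' must have one entry per protein")
  bad <- setdiff(unique(organism), c("host", "phage", "spike_in"))
  if (length(bad))
    gs_format_error(sprintf("unknown organism label(s): %s (allowed: host, phage, spike_in)",
                            paste(bad, collapse = ", ")))
  if (!spike_in_id %in% ids)
    gs_integrity_error(sprintf("spike_in_id '%s' not found among protein ids", spike_in_id))
  if (any(values[spike_in_id, ] <= 0))
    gs_integrity_error(sprintf("spike-in row '%s' must be > 0 in all 21 columns", spike_in_id))
  structure(list(values = values,
                 organism = setNames(as.character(organism), ids),
                 spike_in_id = spike_in_id),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d proteins x 21 columns (F01..F20, P)\n",
              nrow(x$values)))
  cat(sprintf("  spike-in: %s | host: %d, phage: %d\n", x$spike_in_id,
              sum(x$organism == "host"), sum(x$organism == "phage")))
  invisible(x)
}

parse_numeric_cells <- function(df, cols, what) {
  n_missing <- 0L
  for (cc in cols) {
    v <- df[[cc]]
    if (is.character(v)) {
      blank <- is.na(v) | v == "" | v == "NA"
      n_missing <- n_missing + sum(blank)
      v[blank] <- "0"
      num <- suppressWarnings(as.numeric(v))
      if (anyNA(num))
        gs_format_error(sprintf("non-numeric value in column '%s' of %s", cc, what))
      df[[cc]] <- num
    } else {
      blank <- is.na(v)
      n_missing <- n_missing + sum(blank)
      v[blank] <- 0
      df[[cc]] <- as.numeric(v)
    }
  }
  if (n_missing > 0L)
    warning(sprintf("%d missing intensity cell(s) in %s treated as 0 (not detected)",
                    n_missing, what), call. = FALSE)
  df
}

require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    gs_format_error(sprintf("file '%s' is missing required column(s): %s",
                            path, paste(miss, collapse = ", ")))
  invisible(df)
}

count_data_lines <- function(path) {
  n <- length(readLines(path, warn = FALSE))
  max(n - 1L, 0L)  # header
}

#' Read a protein x fraction intensity table
#'
#' Expects a tab-separated file with header
#' `protein_id, F01..F20, P, organism`. Empty or `NA` cells are parsed as 0
#' (not detected) with a warning giving the count.
#'
#' @param path Path to the TSV file.
#' @param spike_in_id Protein id of the spike-in row (e.g. the human albumin
#'   standard).
#' @return A validated [intensity_matrix()] with rows in file order.
#' @export
read_intensity_table <- function(path, spike_in_id) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8")
  require_columns(df, c("protein_id", value_columns(), "organism"), path)
  if (nrow(df) != count_data_lines(path))
    gs_integrity_error(sprintf("row count mismatch reading '%s'", path))
  df <- parse_numeric_cells(df, value_columns(), sprintf("'%s'", path))
  vals <- as.matrix(df[value_columns()])
  rownames(vals) <- df$protein_id
  intensity_matrix(vals, df$organism, spike_in_id)
}

#' Write an intensity matrix to TSV
#'
#' Inverse of [read_intensity_table()]; `read(write(m))` reproduces `m`
#' values to full double precision.
#'
#' @param m An [intensity_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(m, path) {
  df <- data.frame(protein_id = rownames(m$values),
                   m$values,
                   organism = unname(m$organism),
                   check.names = FALSE)
  write_tsv(df, path)
}

write_tsv <- function(df, path) {
  numeric_cols <- vapply(df, is.numeric, logical(1))
  df[numeric_cols] <- lapply(df[numeric_cols], format_full_precision)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

format_full_precision <- function(x) {
  out <- sprintf("%.17g", x)
  out[x == round(x) & abs(x) < 1e15] <- sprintf("%.0f", x[x == round(x) & abs(x) < 1e15])
  out
}

#' Read a protein annotation table
#'
#' Tab-separated, header `protein_id, organism, reference_complex`. The
#' `reference_complex` field must come from
#' [reference_complex_vocabulary()]; an empty field is stored as `"none"`.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of class `"annotation_table"` with columns
#'   `protein_id`, `organism`, `reference_complex`.
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8")
  require_columns(df, c("protein_id", "organism", "reference_complex"), path)
  if (nrow(df) != count_data_lines(path))
    gs_integrity_error(sprintf("row count mismatch reading '%s'", path))
  annotation_table(df$protein_id, df$organism, df$reference_complex)
}

#' Construct and validate an annotation table
#'
#' @param protein_id Unique protein ids.
#' @param organism `"host"` or `"phage"` per protein.
#' @param reference_complex Labels from [reference_complex_vocabulary()];
#'   `NA` or `""` become `"none"`.
#' @return A `data.frame` of class `"annotation_table"`.
#' @export
annotation_table <- function(protein_id, organism,
                             reference_complex = rep("none", length(protein_id))) {
  protein_id <- as.character(protein_id)
  if (anyDuplicated(protein_id))
    gs_integrity_error(sprintf("duplicate protein_id in annotations: %s",
                               protein_id[duplicated(protein_id)][1L]))
  reference_complex <- as.character(reference_complex)
  reference_complex[is.na(reference_complex) | reference_complex == ""] <- "none"
  vocab <- reference_complex_vocabulary()
  bad <- setdiff(unique(reference_complex), vocab)
  if (length(bad))
    gs_format_error(sprintf("unknown reference_complex term(s): %s (allowed: %s)",
                            paste(bad, collapse = ", "),
                            paste(vocab, collapse = ", ")))
  bad_org <- setdiff(unique(as.character(organism)), c("host", "phage"))
  if (length(bad_org))
    gs_format_error(sprintf("unknown organism label(s) in annotations: %s (allowed: host, phage)",
                            paste(bad_org, collapse = ", ")))
  structure(data.frame(protein_id = protein_id,
                       organism = as.character(organism),
                       reference_complex = reference_complex,
                       stringsAsFactors = FALSE),
            class = c("annotation_table", "data.frame"))
}

#' Write an annotation table to TSV
#' @param ann An [annotation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  write_tsv(as.data.frame(ann), path)
}

#' Read a transcript x time-point count table
#'
#' Tab-separated, header `transcript_id, genome, t<min>, ...` with time
#' columns labelled in minutes (`t0, t2, ... t10`) in strictly increasing
#' order. Counts must be non-negative integers.
#'
#' @param path Path to the TSV file.
#' @return A `"counts_timecourse"` object: list with `counts` (integer
#'   matrix transcripts x timepoints), `genome` (named character),
#'   `timepoints` (numeric minutes).
#' @export
read_counts_table <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8")
  require_columns(df, c("transcript_id", "genome"), path)
  if (nrow(df) != count_data_lines(path))
    gs_integrity_error(sprintf("row count mismatch reading '%s'", path))
  tcols <- setdiff(names(df), c("transcript_id", "genome"))
  if (!length(tcols))
    gs_format_error(sprintf("file '%s' has no time-point columns (t0, t2, ...)", path))
  if (!all(grepl("^t[0-9]+$", tcols)))
    gs_format_error(sprintf("time-point columns must be labelled t<minutes>; got: %s",
                            paste(tcols, collapse = ", ")))
  tp <- as.numeric(sub("^t", "", tcols))
  if (any(diff(tp) <= 0))
    gs_format_error(sprintf("time-point columns must be strictly increasing; got: %s",
                            paste(tcols, collapse = ", ")))
  counts <- matrix(0, nrow(df), length(tcols),
                   dimnames = list(df$transcript_id, tcols))
  for (j in seq_along(tcols)) {
    v <- suppressWarnings(as.numeric(df[[tcols[j]]]))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad))
      gs_format_error(sprintf("non-integer or negative count at row %d, column '%s' of '%s'",
                              bad[1L], tcols[j], path))
    counts[, j] <- v
  }
  counts_timecourse(counts, df$genome, tp)
}

#' Construct and validate a time-course count object
#'
#' @param counts Non-negative integer matrix, transcripts x timepoints, with
#'   rownames = transcript ids.
#' @param genome `"host"` or `"phage"` per transcript.
#' @param timepoints Strictly increasing time points, minutes.
#' @return A `"counts_timecourse"` object.
#' @export
counts_timecourse <- function(counts, genome, timepoints) {
  if (!is.matrix(counts)) gs_format_error("'counts' must be a matrix")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    gs_format_error("counts must be finite non-negative integers")
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) != ncol(counts) || any(diff(timepoints) <= 0))
    gs_format_error("'timepoints' must be strictly increasing, one per count column")
  ids <- rownames(counts)
  if (is.null(ids)) gs_format_error("counts must carry transcript ids as rownames")
  if (anyDuplicated(ids))
    gs_integrity_error(sprintf("duplicate transcript_id: %s", ids[duplicated(ids)][1L]))
  bad <- setdiff(unique(as.character(genome)), c("host", "phage"))
  if (length(bad))
    gs_format_error(sprintf("unknown genome label(s): %s (allowed: host, phage)",
                            paste(bad, collapse = ", ")))
  colnames(counts) <- sprintf("t%g", timepoints)
  structure(list(counts = counts,
                 genome = setNames(as.character(genome), ids),
                 timepoints = timepoints),
            class = "counts_timecourse")
}

#' @export
print.counts_timecourse <- function(x, ...) {
  cat(sprintf("<counts_timecourse> %d transcripts (%d phage, %d host) x %d time points (%s min)\n",
              nrow(x$counts), sum(x$genome == "phage"), sum(x$genome == "host"),
              length(x$timepoints), paste(x$timepoints, collapse = ", ")))
  invisible(x)
}

#' Write a time-course count table to TSV
#' @param tc A [counts_timecourse()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(tc, path) {
  df <- data.frame(transcript_id = rownames(tc$counts),
                   genome = unname(tc$genome),
                   tc$counts, check.names = FALSE)
  write_tsv(df, path)
}
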