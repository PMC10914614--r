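# Sedimentation-profile construction: spike-in correction, per-protein
# max-normalization over gradient fractions 1-20, pellet share, abundance
# filter.

#' Correct per-fraction technical scale with the spike-in row
#'
#' Each gradient fraction (and the pellet) receives slightly different
#' amounts of material through collection and MS injection. A constant
#' amount of foreign protein (e.g. 2 pmol human albumin) spiked into every
#' fraction reports that per-column scale. Column `j` of every row is
#' multiplied by `s_ref / s_j`, where `s_j` is the spike-in intensity in
#' column `j` and `s_ref` the median of `s_1..s_21`; the spike-in row itself
#' becomes constant at `s_ref`. The operation is idempotent.
#'
#' @param m An [intensity_matrix()] whose spike-in row is strictly positive
#'   in all 21 columns.
#' @return A corrected [intensity_matrix()].
#' @export
spike_in_normalize <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  s <- m$values[m$spike_in_id, ]
  if (any(s <= 0))
    gs_error("spike-in row has non-positive values; cannot correct",
             "gradsift_degenerate_spike_in")
  s_ref <- median(s)
  corrected <- sweep(m$values, 2L, s_ref / s, `*`)
  # guard against accumulated FP error putting the spike-in row off-constant
  corrected[m$spike_in_id, ] <- s_ref
  intensity_matrix(corrected, m$organism, m$spike_in_id)
}

#' Normalize one raw 21-value row into a sedimentation profile
#'
#' Gradient fractions 1-20 are divided by the maximum over fractions 1-20
#' (so the peak fraction is 1); the pellet is expressed as its share of the
#' protein's total signal. With `pellet_denominator = "total"` (default)
#' that share is `P / (sum(F01..F20) + P)`; `"gradient_only"` uses
#' `P / sum(F01..F20)` capped at 1.
#'
#' A row whose 20 gradient fractions are all zero but whose pellet is
#' positive yields all-zero fractions, `pellet_share` 1 and `peak_fraction`
#' `NA` (the protein sediments entirely in the pellet).
#'
#' @param raw Numeric vector of 21 non-negative values (`F01..F20`, `P`).
#' @param pellet_denominator `"total"` or `"gradient_only"`.
#' @return A list with `fractions` (20 values, max 1), `pellet_share`,
#'   `total_intensity` (sum over all 21 raw values) and `peak_fraction`
#'   (smallest index attaining the maximum).
#' @export
normalize_profile <- function(raw, pellet_denominator = c("total", "gradient_only")) {
  pellet_denominator <- match.arg(pellet_denominator)
  raw <- as.numeric(raw)
  if (length(raw) != 21L || any(!is.finite(raw)) || any(raw < 0))
    gs_format_error("'raw' must be 21 finite non-negative values (F01..F20, P)")
  if (all(raw == 0))
    gs_error("all-zero row has no sedimentation profile",
             "gradsift_empty_profile")
  frac <- raw[1:20]
  pellet <- raw[21]
  mx <- max(frac)
  fractions <- if (mx > 0) frac / mx else rep(0, 20)
  denom <- switch(pellet_denominator,
                  total = sum(frac) + pellet,
                  gradient_only = sum(frac))
  pellet_share <- if (denom > 0) min(pellet / denom, 1) else 1
  list(fractions = fractions,
       pellet_share = pellet_share,
       total_intensity = sum(raw),
       peak_fraction = if (mx > 0) which.max(frac) else NA_integer_)
}

#' Build sedimentation profiles for every protein in a matrix
#'
#' Applies [normalize_profile()] row-wise after (optionally already done)
#' spike-in correction. All-zero rows are dropped with a warning naming how
#' many, since a protein never detected in any fraction has no profile.
#'
#' @param m An [intensity_matrix()], normally the output of
#'   [spike_in_normalize()].
#' @param pellet_denominator Passed to [normalize_profile()].
#' @return A `data.frame` of class `"sedimentation_profiles"`: columns
#'   `protein_id`, `F01..F20` (normalized, peak = 1), `pellet_share`,
#'   `total_intensity`, `peak_fraction`, `organism`.
#' @export
normalize_profiles <- function(m, pellet_denominator = c("total", "gradient_only")) {
  stopifnot(inherits(m, "intensity_matrix"))
  pellet_denominator <- match.arg(pellet_denominator)
  keep <- rowSums(m$values) > 0
  if (any(!keep))
    warning(sprintf("%d all-zero row(s) dropped (no sedimentation profile)",
                    sum(!keep)), call. = FALSE)
  vals <- m$values[keep, , drop = FALSE]
  frac <- vals[, 1:20, drop = FALSE]
  pellet <- vals[, 21]
  mx <- apply(frac, 1L, max)
  norm <- frac / ifelse(mx > 0, mx, 1)
  norm[mx == 0, ] <- 0
  denom <- switch(pellet_denominator,
                  total = rowSums(frac) + pellet,
                  gradient_only = rowSums(frac))
  pellet_share <- ifelse(denom > 0, pmin(pellet / denom, 1), 1)
  peak <- apply(frac, 1L, which.max)
  peak[mx == 0] <- NA_integer_
  out <- data.frame(protein_id = rownames(vals), norm,
                    pellet_share = pellet_share,
                    total_intensity = rowSums(vals),
                    peak_fraction = as.integer(peak),
                    organism = unname(m$organism[keep]),
                    check.names = FALSE, row.names = NULL)
  structure(out, class = c("sedimentation_profiles", "data.frame"),
            spike_in_id = m$spike_in_id)
}

#' Keep only proteins above the abundance filter
#'
#' Retains proteins with `log10(total_intensity) > threshold_log10` on the
#' spike-in-corrected scale (strict inequality). The spike-in row is always
#' excluded regardless of its abundance. The default threshold of 8.0
#' mirrors the usual relative log10 iBAQ cut applied before clustering
#' gradient proteomes.
#'
#' @param profiles A `"sedimentation_profiles"` data.frame.
#' @param threshold_log10 Abundance cut on `log10(total_intensity)`.
#' @return The retained subset, same class. May be empty.
#' @export
filter_by_abundance <- function(profiles, threshold_log10 = 8.0) {
  stopifnot(inherits(profiles, "sedimentation_profiles"))
  spike <- attr(profiles, "spike_in_id")
  keep <- log10(profiles$total_intensity) > threshold_log10 &
    profiles$organism != "spike_in"
  if (!is.null(spike)) keep <- keep & profiles$protein_id != spike
  out <- profiles[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "spike_in_id") <- spike
  class(out) <- class(profiles)
  out
}

#' Extract the n x 20 normalized fraction matrix from profiles
#' @param profiles A `"sedimentation_profiles"` data.frame.
#' @return Numeric matrix with protein ids as rownames.
#' @export
fraction_matrix <- function(profiles) {
  m <- as.matrix(profiles[, fraction_labels(), drop = FALSE])
  rownames(m) <- profiles$protein_id
  m
}

#' Write sedimentation profiles to TSV
#' @param profiles A `"sedimentation_profiles"` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  write_tsv(as.data.frame(profiles), path)
}

#' Read sedimentation profiles written by [write_profiles()]
#' @param path Path to the TSV file.
#' @return A `"sedimentation_profiles"` data.frame.
#' @export
read_profiles <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   fileEncoding = "UTF-8")
  require_columns(df, c("protein_id", fraction_labels(), "pellet_share",
                        "total_intensity", "peak_fraction", "organism"), path)
  df$peak_fraction <- as.integer(df$peak_fraction)
  structure(df, class = c("sedimentation_profiles", "data.frame"))
}
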