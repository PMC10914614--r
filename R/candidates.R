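# Candidate calling: nominate phage proteins as ribosome-associated
# factors. The rule mirrors how such factors stand out in a gradient:
# they leave the low-molecular-weight top of the gradient (peak deep
# enough to be complexed), co-sediment with a ribosomal subunit, and are
# not pellet-heavy (pellet-heavy phage proteins are typically virion
# assembly intermediates, not soluble ribosome binders).

#' Flag a profile as high molecular weight
#'
#' The first three gradient fractions hold free proteins and small (<100
#' kDa) complexes; a protein peaking at `hmw_min_fraction` (default 4) or
#' deeper is considered part of a larger particle.
#'
#' @param profiles A `"sedimentation_profiles"` data.frame (or an integer
#'   vector of peak fractions).
#' @param hmw_min_fraction Smallest peak fraction that counts as HMW.
#' @return Logical vector, `NA` peaks (all-pellet proteins) give `FALSE`.
#' @export
flag_hmw <- function(profiles, hmw_min_fraction = 4L) {
  peak <- if (is.numeric(profiles)) as.integer(profiles)
          else profiles$peak_fraction
  out <- !is.na(peak) & peak >= hmw_min_fraction
  names(out) <- if (is.data.frame(profiles)) profiles$protein_id else names(profiles)
  out
}

#' Call phage proteins as ribosome-associated candidates
#'
#' A phage protein passes when it (i) peaks in HMW fractions, (ii) is
#' assigned to a ribosomal-subunit centroid (30S or 50S) at `r_min`, and
#' (iii) has pellet share at most `pellet_max` (so virion assembly
#' intermediates, which accumulate in the pellet, are excluded).
#'
#' @param profiles A `"sedimentation_profiles"` data.frame.
#' @param assignments A `"complex_assignments"` data.frame from
#'   [assign_to_reference()], computed with the same `r_min`.
#' @param organism_filter Which organism's proteins to screen (default
#'   `"phage"`).
#' @param pellet_max Maximum tolerated pellet share (default 0.2).
#' @param hmw_min_fraction Passed to [flag_hmw()].
#' @return A `data.frame` of class `"candidate_calls"` with one row per
#'   screened protein: `protein_id`, `is_hmw`, `pellet_share`,
#'   `assigned_label`, `subunit_class` (`"30S"`, `"50S"` or `"none"`),
#'   `score`, `passes`; passing rows first, sorted by score descending.
#' @export
call_ribosome_candidates <- function(profiles, assignments,
                                     organism_filter = "phage",
                                     pellet_max = 0.2,
                                     hmw_min_fraction = 4L) {
  stopifnot(inherits(profiles, "sedimentation_profiles"),
            inherits(assignments, "complex_assignments"))
  idx <- profiles$organism == organism_filter
  prof <- profiles[idx, , drop = FALSE]
  m <- match(prof$protein_id, assignments$protein_id)
  if (anyNA(m))
    gs_integrity_error(sprintf("no assignment for protein(s): %s",
                               paste(utils::head(prof$protein_id[is.na(m)], 3L),
                                     collapse = ", ")))
  asg <- assignments[m, , drop = FALSE]
  is_hmw <- flag_hmw(prof, hmw_min_fraction)
  ribosomal <- asg$label %in% c("30S", "50S")
  passes <- unname(is_hmw) & ribosomal & prof$pellet_share <= pellet_max
  out <- data.frame(protein_id = prof$protein_id,
                    is_hmw = unname(is_hmw),
                    pellet_share = prof$pellet_share,
                    assigned_label = asg$label,
                    subunit_class = ifelse(ribosomal, asg$label, "none"),
                    score = asg$score,
                    passes = passes,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$passes, -out$score, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("candidate_calls", "data.frame"),
            pellet_max = pellet_max, hmw_min_fraction = hmw_min_fraction)
}

#' Classify a profile as 30S- or 50S-targeting
#'
#' Compares the Pearson correlation of a profile against the 30S and 50S
#' centroids and returns the better-correlated subunit. A near-exact tie
#' (`|r_30S - r_50S| < 1e-9`) cannot be resolved from the profile alone:
#' the function returns `NA` and signals a warning of class
#' `"gradsift_ambiguous_subunit"` so the case is routed to manual review.
#'
#' @param profile A 20-vector, [normalize_profile()] result, or single
#'   profile row.
#' @param centroid_30S,centroid_50S Numeric 20-vectors (rows of a
#'   `"reference_centroids"` matrix).
#' @return `"30S"`, `"50S"`, or `NA_character_` on a tie.
#' @export
classify_subunit <- function(profile, centroid_30S, centroid_50S) {
  p <- as_fraction_vector(profile)
  r30 <- pearson_or_error(p, as_fraction_vector(centroid_30S))
  r50 <- pearson_or_error(p, as_fraction_vector(centroid_50S))
  if (abs(r30 - r50) < 1e-9) {
    warning(warningCondition(
      "30S and 50S correlations tie; subunit class needs manual review",
      class = "gradsift_ambiguous_subunit"))
    return(NA_character_)
  }
  if (r30 > r50) "30S" else "50S"
}

#' Write candidate calls to JSON
#' @param calls A `"candidate_calls"` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(calls, path) {
  jsonlite::write_json(as.data.frame(calls), path, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
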