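# Infection time-course analysis: per-genome CDS read fractions, phage
# transcript ranking with a cumulative-abundance cut-off, and candidate
# prioritization by early expression.

#' Phage share of reads at each time point
#'
#' For every time point, the fraction of CDS reads mapping to the phage
#' genome: `phage counts / total counts`.
#'
#' @param tc A [counts_timecourse()].
#' @return Named numeric vector (one value per time point) in `[0, 1]`.
#' @export
genome_read_fraction <- function(tc) {
  stopifnot(inherits(tc, "counts_timecourse"))
  total <- colSums(tc$counts)
  if (any(total == 0))
    gs_error(sprintf("zero total counts at time point(s): %s",
                     paste(colnames(tc$counts)[total == 0], collapse = ", ")),
             "gradsift_undefined_fraction")
  phage <- colSums(tc$counts[tc$genome == "phage", , drop = FALSE])
  phage / total
}

#' Rank phage transcripts and mark the cumulative top set
#'
#' Phage transcripts are ranked by their summed counts over the time window
#' (descending; ties broken by transcript id). The top set is the minimal
#' prefix of this ranking whose cumulative share of total phage reads
#' strictly exceeds `cutoff` (default: > 85% of total phage reads).
#'
#' @param tc A [counts_timecourse()].
#' @param window Numeric length-2 time range in minutes (inclusive),
#'   default `c(0, 10)`.
#' @param cutoff Cumulative-share cut-off in `(0, 1)`, strict (`>`).
#' @return A `data.frame` of class `"transcript_ranks"`: `transcript_id`,
#'   `genome`, `window_counts`, `share`, `cum_share`, `rank`,
#'   `in_top_set`; phage shares sum to 1.
#' @export
rank_transcripts_cumulative <- function(tc, window = c(0, 10), cutoff = 0.85) {
  stopifnot(inherits(tc, "counts_timecourse"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff >= 1)
    gs_parameter_error("'cutoff' must lie strictly inside (0, 1)")
  if (length(window) != 2L || window[2] < window[1])
    gs_parameter_error("'window' must be an increasing time range c(from, to)")
  in_win <- tc$timepoints >= window[1] & tc$timepoints <= window[2]
  if (!any(in_win))
    gs_parameter_error("no time points fall inside 'window'")
  phage_idx <- tc$genome == "phage"
  counts <- rowSums(tc$counts[phage_idx, in_win, drop = FALSE])
  if (sum(counts) == 0)
    gs_error("no phage transcript has nonzero counts in the window",
             "gradsift_undefined_fraction")
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  share <- counts / sum(counts)
  cum <- cumsum(share)
  top_n <- which(cum > cutoff)[1L]
  out <- data.frame(transcript_id = names(counts),
                    genome = "phage",
                    window_counts = unname(counts),
                    share = unname(share),
                    cum_share = unname(cum),
                    rank = seq_along(counts),
                    in_top_set = seq_along(counts) <= top_n,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("transcript_ranks", "data.frame"),
            window = window, cutoff = cutoff)
}

#' Order ribosome-candidate proteins by early transcript abundance
#'
#' Joins passing candidate calls to the phage transcript ranking through a
#' protein-to-transcript map and sorts by (`in_top_set` desc, transcript
#' rank asc, co-sedimentation score desc): a candidate whose mRNA is among
#' the most abundant early transcripts outranks any candidate outside the
#' top set. Candidates without a mapped/ranked transcript sort last and
#' are flagged `unmapped`.
#'
#' @param candidates A `"candidate_calls"` data.frame; only rows with
#'   `passes == TRUE` are prioritized.
#' @param ranks A `"transcript_ranks"` data.frame.
#' @param gene_map `data.frame` with columns `protein_id`, `transcript_id`.
#' @return A `data.frame` of class `"candidate_priorities"`, one row per
#'   passing candidate in priority order, with `priority` = 1, 2, ...
#' @export
prioritize_candidates <- function(candidates, ranks, gene_map) {
  stopifnot(inherits(candidates, "candidate_calls"),
            inherits(ranks, "transcript_ranks"))
  if (!all(c("protein_id", "transcript_id") %in% names(gene_map)))
    gs_format_error("'gene_map' needs columns protein_id, transcript_id")
  cand <- candidates[candidates$passes, , drop = FALSE]
  tx <- gene_map$transcript_id[match(cand$protein_id, gene_map$protein_id)]
  m <- match(tx, ranks$transcript_id)
  out <- data.frame(protein_id = cand$protein_id,
                    transcript_id = tx,
                    subunit_class = cand$subunit_class,
                    score = cand$score,
                    transcript_rank = ranks$rank[m],
                    in_top_set = ranks$in_top_set[m],
                    unmapped = is.na(m),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$in_top_set[out$unmapped] <- FALSE
  ord <- order(out$unmapped,                 # mapped before unmapped
               -out$in_top_set,
               ifelse(is.na(out$transcript_rank), Inf, out$transcript_rank),
               -out$score,
               out$protein_id)
  out <- out[ord, , drop = FALSE]
  out$priority <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("candidate_priorities", "data.frame"))
}
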