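# Co-sedimentation clustering: correlation distance between sedimentation
# profiles, deterministic agglomerative clustering, reference centroids for
# the host machineries, and correlation-based machinery assignment.
#
# The pellet is excluded from all correlations: it is on a different
# normalization scale (share of total) than the max-normalized fractions.

as_fraction_vector <- function(p) {
  if (is.list(p) && !is.data.frame(p) && !is.null(p$fractions)) p <- p$fractions
  if (is.data.frame(p)) p <- as.numeric(p[1L, fraction_labels()])
  p <- as.numeric(p)
  if (length(p) != 20L || any(!is.finite(p)))
    gs_format_error("a profile must provide 20 finite fraction values")
  p
}

pearson_or_error <- function(p, q) {
  if (stats::sd(p) == 0 || stats::sd(q) == 0)
    gs_error("zero-variance profile: Pearson correlation undefined",
             "gradsift_undefined_correlation")
  cor(p, q)
}

#' Correlation distance between two sedimentation profiles
#'
#' Returns `1 - Pearson r` computed over the 20 gradient-fraction values
#' (pellet excluded), in `[0, 2]`.
#'
#' @param p,q Profiles: numeric 20-vectors, [normalize_profile()] results,
#'   or single rows of a `"sedimentation_profiles"` data.frame.
#' @return Distance in `[0, 2]`.
#' @export
profile_distance <- function(p, q) {
  1 - pearson_or_error(as_fraction_vector(p), as_fraction_vector(q))
}

profile_distance_matrix <- function(X) {
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0))
    gs_error(sprintf("zero-variance profile(s): %s",
                     paste(utils::head(rownames(X)[sds == 0], 3L), collapse = ", ")),
             "gradsift_undefined_correlation")
  D <- 1 - cor(t(X))
  D[D < 0] <- 0  # clamp FP noise on perfectly correlated pairs
  diag(D) <- 0
  D
}

# Agglomeration with a fixed convention so merge order is reproducible:
# a cluster is identified by the smallest original row index among its
# members; at each step the pair with minimal linkage merges, ties broken
# by the lexicographically smallest (i, j) id pair; the merged cluster
# keeps the smaller id. Linkage values are updated by Lance-Williams.
agglomerate <- function(D, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  n <- nrow(D)
  if (n < 2L) gs_parameter_error("need at least 2 profiles to cluster")
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  members <- as.list(seq_len(n))
  W <- D
  diag(W) <- Inf
  W[!is.finite(D) & row(D) != col(D)] <- Inf
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  assignment <- seq_len(n)
  steps <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    W_act <- W
    W_act[!active, ] <- Inf
    W_act[, !active] <- Inf
    mn <- min(W_act)
    hits <- which(W_act == mn, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    merges[s, ] <- c(i, j)
    heights[s] <- mn
    others <- which(active & seq_len(n) != i & seq_len(n) != j)
    if (length(others)) {
      upd <- switch(linkage,
        average = (size[i] * W[i, others] + size[j] * W[j, others]) /
                  (size[i] + size[j]),
        complete = pmax(W[i, others], W[j, others]))
      W[i, others] <- upd
      W[others, i] <- upd
    }
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    assignment[assignment == j] <- i
    steps[[s]] <- assignment
  }
  list(merges = merges, heights = heights, steps = steps)
}

#' Agglomeratively cluster sedimentation profiles into k groups
#'
#' Clusters the 20-dimensional normalized fraction vectors on correlation
#' distance (`1 - Pearson r`) with average or complete linkage. The merge
#' order is fully deterministic: ties break to the lowest pair of cluster
#' indices, where a cluster is indexed by its smallest original row.
#'
#' @param profiles A `"sedimentation_profiles"` data.frame (or an n x 20
#'   numeric matrix).
#' @param k Number of flat clusters, `2 <= k <= n` (k = n gives singletons).
#' @param linkage `"average"` (default) or `"complete"`.
#' @return Integer vector of cluster labels (1..k, numbered by first
#'   appearance), named by protein id. The full merge history is attached
#'   as attributes `merges` and `heights`.
#' @export
hierarchical_cluster <- function(profiles, k, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  X <- if (is.matrix(profiles)) profiles else fraction_matrix(profiles)
  n <- nrow(X)
  if (k < 1L || k > n)
    gs_parameter_error(sprintf("k = %d outside 1..n (n = %d)", k, n))
  if (k == n) {
    labels <- setNames(seq_len(n), rownames(X))
    return(labels)
  }
  res <- agglomerate(profile_distance_matrix(X), linkage)
  assignment <- res$steps[[n - k]]
  labels <- match(assignment, unique(assignment))
  labels <- setNames(as.integer(labels), rownames(X))
  attr(labels, "merges") <- res$merges
  attr(labels, "heights") <- res$heights
  labels
}

#' Mean sedimentation profile of each annotated reference machinery
#'
#' Averages the normalized fraction vectors of the annotated members of
#' each reference complex (30S, 50S, RNAP, other) present in the
#' annotation table. Every annotated label must have at least 3 members
#' among the (abundance-filtered) profiles, otherwise the centroid would
#' not be trustworthy.
#'
#' @param profiles A `"sedimentation_profiles"` data.frame, normally after
#'   [filter_by_abundance()].
#' @param annotations An [annotation_table()].
#' @return An object of class `"reference_centroids"`: list with `centroids`
#'   (label x 20 matrix, entries in `[0, 1]`) and `n_members` (named
#'   integer).
#' @export
build_reference_centroids <- function(profiles, annotations) {
  stopifnot(inherits(profiles, "sedimentation_profiles"),
            inherits(annotations, "annotation_table"))
  ref <- annotations[annotations$reference_complex != "none", , drop = FALSE]
  labels <- intersect(reference_complex_vocabulary(),
                      unique(ref$reference_complex))
  if (!length(labels))
    gs_error("no annotated reference-complex members available",
             "gradsift_insufficient_reference")
  X <- fraction_matrix(profiles)
  centroids <- matrix(NA_real_, length(labels), 20L,
                      dimnames = list(labels, fraction_labels()))
  n_members <- setNames(integer(length(labels)), labels)
  for (lab in labels) {
    ids <- intersect(ref$protein_id[ref$reference_complex == lab],
                     rownames(X))
    if (length(ids) < 3L)
      gs_error(sprintf("reference complex '%s' has %d member(s) passing the filter; >= 3 required",
                       lab, length(ids)),
               "gradsift_insufficient_reference")
    centroids[lab, ] <- colMeans(X[ids, , drop = FALSE])
    n_members[lab] <- length(ids)
  }
  structure(list(centroids = centroids, n_members = n_members),
            class = "reference_centroids")
}

#' @export
print.reference_centroids <- function(x, ...) {
  cat(sprintf("<reference_centroids> %s\n",
              paste(sprintf("%s (n=%d, peak F%02d)", rownames(x$centroids),
                            x$n_members, apply(x$centroids, 1L, which.max)),
                    collapse = ", ")))
  invisible(x)
}

#' Assign each profile to the best-correlated reference machinery
#'
#' Computes Pearson r between every profile's 20 normalized fraction values
#' and each reference centroid; a protein is labelled with the
#' highest-correlating machinery if that correlation reaches `r_min`,
#' otherwise `"unassigned"`.
#'
#' @param profiles A `"sedimentation_profiles"` data.frame.
#' @param centroids A `"reference_centroids"` object.
#' @param r_min Minimum Pearson r to accept an assignment (default 0.8).
#' @return A `data.frame` of class `"complex_assignments"`: `protein_id`,
#'   `label` (centroid label or `"unassigned"`), `score` (the maximal r),
#'   `organism`.
#' @export
assign_to_reference <- function(profiles, centroids, r_min = 0.8) {
  stopifnot(inherits(profiles, "sedimentation_profiles"),
            inherits(centroids, "reference_centroids"))
  X <- fraction_matrix(profiles)
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0))
    gs_error(sprintf("zero-variance profile(s): %s",
                     paste(utils::head(rownames(X)[sds == 0], 3L), collapse = ", ")),
             "gradsift_undefined_correlation")
  R <- cor(t(X), t(centroids$centroids))  # n x n_labels
  best <- max.col(R, ties.method = "first")
  score <- R[cbind(seq_len(nrow(R)), best)]
  label <- colnames(R)[best]
  label[score < r_min] <- "unassigned"
  structure(data.frame(protein_id = profiles$protein_id,
                       label = label,
                       score = score,
                       organism = profiles$organism,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("complex_assignments", "data.frame"),
            r_min = r_min)
}
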