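# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately use naive, from-scratch formulations so they share
# no code path with the implementation they check.

# Textbook Pearson correlation from sum formulas.
pearson_textbook <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Exhaustive agglomeration: clusters as member sets, identified by their
# smallest original index; every step recomputes all pairwise linkage
# values from the raw distance matrix. Returns the merge-id sequence.
brute_force_agglomerate <- function(D, linkage = "average") {
  clusters <- as.list(seq_len(nrow(D)))
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        vals <- D[as.matrix(expand.grid(clusters[[a]], clusters[[b]]))]
        lv <- if (linkage == "average") mean(vals) else max(vals)
        ids <- sort(c(min(clusters[[a]]), min(clusters[[b]])))
        better <- is.null(best) || lv < best$lv ||
          (lv == best$lv && (ids[1] < best$ids[1] ||
                               (ids[1] == best$ids[1] && ids[2] < best$ids[2])))
        if (better) best <- list(lv = lv, a = a, b = b, ids = ids)
      }
    }
    merges[[length(merges) + 1L]] <- best$ids
    clusters[[best$a]] <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    clusters[[best$b]] <- NULL
  }
  do.call(rbind, merges)
}

# Minimal prefix of the sorted shares whose cumulative sum strictly
# exceeds the cutoff.
top_set_size_oracle <- function(counts, cutoff) {
  shares <- sort(counts / sum(counts), decreasing = TRUE)
  total <- 0
  for (i in seq_along(shares)) {
    total <- total + shares[i]
    if (total > cutoff) return(i)
  }
  length(shares)
}

# Step-by-step Beer-Lambert arithmetic: molarity -> moles -> molecules ->
# per cell.
ribosomes_per_cell_oracle <- function(a260, volume_l, n_cells,
                                      epsilon = 3.84e7, path_cm = 1) {
  molar <- a260 / epsilon / path_cm
  moles <- molar * volume_l
  molecules <- moles * 6.02214076e23
  molecules / n_cells
}

# A tiny 3-protein intensity matrix with a constant spike-in.
toy_intensity_matrix <- function() {
  vals <- rbind(
    host_a  = c(0, 0, 4, 8, 4, rep(0, 15), 4),
    phage_b = c(10, rep(0, 19), 0),
    spike   = rep(100, 21))
  gradsift::intensity_matrix(vals, c("host", "phage", "spike_in"), "spike")
}

# Handmade random non-negative intensity rows (21 columns), at least one
# positive value each.
random_rows <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * 21, 0, 100) * rbinom(n * 21, 1, 0.7), n, 21)
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  m
}
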