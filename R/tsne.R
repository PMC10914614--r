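# Diagnostic 2-D embedding of sedimentation profiles.
#
# Exact (non-Barnes-Hut) t-SNE on the 20-dimensional normalized fraction
# vectors. Gradient-fraction profile sets are small (hundreds of proteins),
# so the O(n^2) formulation is both adequate and simple to make
# bit-reproducible. The embedding is for visual inspection of
# co-sedimentation structure only; machinery assignment always goes through
# assign_to_reference().

perplexity_to_P <- function(D2, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; beta_min <- -Inf; beta_max <- Inf
    di <- D2[i, -i]
    for (it in seq_len(max_iter)) {
      p <- exp(-di * beta)
      sum_p <- sum(p)
      if (sum_p == 0) { h <- 0; p_norm <- p }
      else {
        p_norm <- p / sum_p
        h <- -sum(p_norm[p_norm > 0] * log(p_norm[p_norm > 0]))
      }
      diff <- h - log_u
      if (abs(diff) < tol) break
      if (diff > 0) {  # entropy too high -> sharpen
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p_norm
  }
  P
}

#' Embed sedimentation profiles in 2-D (t-SNE)
#'
#' Exact t-SNE of the n x 20 normalized fraction vectors, seeded and
#' bit-reproducible: the same `seed` always returns identical coordinates.
#' Proteins with correlated sedimentation profiles land close together, so
#' machinery-sized clusters become visible; the embedding is diagnostic and
#' is never used for assignment.
#'
#' @param profiles A `"sedimentation_profiles"` data.frame or an n x 20
#'   numeric matrix.
#' @param seed Integer seed for the embedding initialization.
#' @param perplexity Effective neighbourhood size; requires
#'   `n >= 3 * perplexity`.
#' @param n_iter Gradient-descent iterations (default 500).
#' @return An n x 2 numeric matrix of coordinates, rownames = protein ids.
#' @export
embed_2d <- function(profiles, seed = 42L, perplexity = 30, n_iter = 500L) {
  X <- if (is.matrix(profiles)) profiles else fraction_matrix(profiles)
  n <- nrow(X)
  if (n < 3L) gs_parameter_error("need at least 3 profiles to embed")
  if (n < 3 * perplexity)
    gs_parameter_error(sprintf("perplexity %g too large for n = %d (need n >= 3*perplexity)",
                               perplexity, n))
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  P <- perplexity_to_P(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(as.integer(seed))
  Y <- matrix(rnorm(n * 2L, sd = 1e-4), n, 2L)
  dY <- matrix(0, n, 2L)
  gains <- matrix(1, n, 2L)
  eta <- 200
  exaggeration <- 12
  for (iter in seq_len(n_iter)) {
    Pe <- if (iter <= 100L) P * exaggeration else P
    sqy <- rowSums(Y^2)
    num <- 1 / (1 + outer(sqy, sqy, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
    momentum <- if (iter < 250L) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  dimnames(Y) <- list(rownames(X), c("x", "y"))
  Y
}
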