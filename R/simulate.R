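# Truth-labelled synthetic data: a gradient proteome with known complex
# memberships, and an infection time course with known expression classes.
#
# Sedimentation model: each protein's gradient mass follows a Gaussian
# evaluated at integer fraction indices 1..20 and renormalized to sum 1
# ("fraction-index space"; no physical Svedberg modelling). The pellet is a
# separate compartment receiving a class-specific share of the protein's
# mass. Technical structure mimics iBAQ data: a per-fraction lognormal
# scale factor d_j (corrected later by the constant spike-in), per-cell
# multiplicative lognormal noise, and a hard detection limit (dropout).
#
# Reproducibility: one global seed feeds a per-protein derived seed, so
# the same protein gets the same draws regardless of row order or of the
# settings of other knobs (in particular, biological noise draws do not
# change when the technical scale-factor spread is changed).

default_gradient_classes <- function() {
  data.frame(
    label     = c("host_free", "host_RNAP", "host_30S", "host_50S", "host_70S",
                  "phage_free", "phage_nvRNAP", "phage_30S_binder",
                  "phage_50S_binder", "phage_virion"),
    organism  = c(rep("host", 5), rep("phage", 5)),
    n         = c(280L, 30L, 25L, 35L, 30L, 21L, 5L, 3L, 5L, 6L),
    center    = c(2, 5, 11, 14, 17, 2, 5, 11, 14, 18),
    width     = c(1.0, 1.0, 1.2, 1.3, 2.0, 1.0, 1.0, 1.2, 1.3, 1.5),
    pellet_mass = c(0, 0.02, 0.05, 0.05, 0.2, 0, 0.02, 0.05, 0.05, 0.9),
    machinery = c("none", "RNAP", "30S", "50S", "other",
                  "none", "RNAP", "30S", "50S", "virion"),
    # gene-expression machinery carries a large share of cellular protein
    # mass, so complexed classes sit in a higher iBAQ band than the bulk
    abund_lo  = c(7.5, 8.5, 8.5, 8.5, 8.5, 7.5, 8.3, 8.3, 8.3, 8.3),
    abund_hi  = c(9.0, 9.8, 9.8, 9.8, 9.8, 9.0, 9.5, 9.5, 9.5, 9.5),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic gradient proteome
#'
#' Defaults give ~440 proteins: 400 host (280 free at fraction 2, 30
#' RNAP-like at 5, 25 30S-like at 11, 35 50S-like at 14, 30 70S/polysome-
#' like at 17) and 40 phage (21 free, 5 nvRNAP-like, 8 planted ribosome
#' binders of which 3 target the 30S and 5 the 50S, 6 pellet-heavy virion
#' proteins).
#'
#' @param classes Data.frame of protein classes (label, organism, n,
#'   center, width, pellet_mass, machinery, abund_lo, abund_hi). Widths
#'   must exceed 0.3 (narrower peaks are unidentifiable at one-fraction
#'   resolution).
#' @param free_fraction Share of each complexed protein's mass in a free
#'   (LMW) pool at fraction 2 (default 0.1).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal MS noise (default 0.2).
#' @param fraction_scale_sd sdlog of the per-fraction technical scale
#'   factor d_j (default 0.3).
#' @param dropout_rel Detection limit as a fraction of the median nonzero
#'   underlying signal (default 0.001, i.e. 0.1%).
#' @param spike_in_level True constant intensity of the spike-in row.
#' @param seed Integer seed.
#' @return A `"sim_gradient_config"` list.
#' @export
sim_gradient_config <- function(classes = default_gradient_classes(),
                                free_fraction = 0.1,
                                noise_cv = 0.2,
                                fraction_scale_sd = 0.3,
                                dropout_rel = 0.001,
                                spike_in_level = 1e9,
                                seed = 42L) {
  needed <- c("label", "organism", "n", "center", "width", "pellet_mass",
              "machinery", "abund_lo", "abund_hi")
  miss <- setdiff(needed, names(classes))
  if (length(miss))
    gs_parameter_error(sprintf("'classes' missing column(s): %s",
                               paste(miss, collapse = ", ")))
  if (any(classes$width <= 0.3))
    gs_parameter_error("'width' must exceed 0.3 for every class")
  if (any(classes$center < 1 | classes$center > 20))
    gs_parameter_error("'center' must lie in [1, 20]")
  if (any(classes$pellet_mass < 0 | classes$pellet_mass > 1))
    gs_parameter_error("'pellet_mass' must lie in [0, 1]")
  if (free_fraction < 0 || free_fraction > 1)
    gs_parameter_error("'free_fraction' must lie in [0, 1]")
  if (noise_cv < 0) gs_parameter_error("'noise_cv' must be >= 0")
  if (fraction_scale_sd < 0) gs_parameter_error("'fraction_scale_sd' must be >= 0")
  check_scalar_positive(spike_in_level, "spike_in_level")
  structure(list(classes = classes, free_fraction = free_fraction,
                 noise_cv = noise_cv, fraction_scale_sd = fraction_scale_sd,
                 dropout_rel = dropout_rel, spike_in_level = spike_in_level,
                 seed = as.integer(seed)),
            class = "sim_gradient_config")
}

gaussian_shape <- function(center, width) {
  g <- stats::dnorm(1:20, mean = center, sd = width)
  g / sum(g)
}

#' Simulate a gradient proteome with known complex structure
#'
#' @param cfg A [sim_gradient_config()].
#' @return List with `matrix` (an [intensity_matrix()] including the
#'   spike-in row `SPIKE_ALB`) and `truth` (data.frame: `protein_id`,
#'   `class`, `organism`, `machinery`, `center`, `pellet_mass`,
#'   `abundance`, `is_ribosome_binder`).
#' @export
simulate_gradient <- function(cfg = sim_gradient_config()) {
  stopifnot(inherits(cfg, "sim_gradient_config"))
  cl <- cfg$classes
  n_total <- sum(cl$n)
  free_shape <- gaussian_shape(2, 1.0)
  sdlog_noise <- sqrt(log(1 + cfg$noise_cv^2))

  set.seed(mix_seed(cfg$seed, 1L))
  d <- rlnorm(21L, 0, cfg$fraction_scale_sd)

  ids <- character(n_total)
  raw_underlying <- matrix(0, n_total, 21L)  # clean * biological noise, pre-d
  truth <- vector("list", nrow(cl))
  p <- 0L
  for (k in seq_len(nrow(cl))) {
    shape <- gaussian_shape(cl$center[k], cl$width[k])
    is_free_class <- cl$machinery[k] == "none" && cl$pellet_mass[k] == 0
    w_complex <- if (is_free_class) 0 else 1 - cfg$free_fraction
    mix <- w_complex * shape + (1 - w_complex) * free_shape
    abund <- numeric(cl$n[k])
    for (i in seq_len(cl$n[k])) {
      p <- p + 1L
      ids[p] <- sprintf("%s_%03d", cl$label[k], i)
      set.seed(mix_seed(cfg$seed, 2L, p))
      A <- 10^runif(1L, cl$abund_lo[k], cl$abund_hi[k])
      abund[i] <- A
      eps <- if (cfg$noise_cv > 0)
        rlnorm(21L, -sdlog_noise^2 / 2, sdlog_noise) else rep(1, 21L)
      clean <- c(A * mix, A * w_complex * cl$pellet_mass[k])
      raw_underlying[p, ] <- clean * eps
    }
    truth[[k]] <- data.frame(
      protein_id = ids[(p - cl$n[k] + 1L):p],
      class = cl$label[k], organism = cl$organism[k],
      machinery = cl$machinery[k], center = cl$center[k],
      pellet_mass = cl$pellet_mass[k], abundance = abund,
      is_ribosome_binder = cl$organism[k] == "phage" &
        cl$machinery[k] %in% c("30S", "50S"),
      stringsAsFactors = FALSE)
  }
  # detection limit on the underlying (pre-technical-scaling) signal so the
  # dropout pattern does not depend on the d_j draws
  if (cfg$dropout_rel > 0) {
    thr <- cfg$dropout_rel * median(raw_underlying[raw_underlying > 0])
    raw_underlying[raw_underlying < thr] <- 0
  }
  values <- sweep(raw_underlying, 2L, d, `*`)
  values <- rbind(values, cfg$spike_in_level * d)
  rownames(values) <- c(ids, "SPIKE_ALB")
  organism <- c(rep(cl$organism, cl$n), "spike_in")
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(matrix = intensity_matrix(values, organism, "SPIKE_ALB"),
       truth = truth)
}

#' Annotation table from simulation truth
#'
#' Builds the annotation table an analyst would realistically have: host
#' proteins carry their machinery label (30S, 50S, RNAP, other); phage
#' proteins are annotated `"none"` (their associations are what the screen
#' must discover).
#'
#' @param truth Truth data.frame from [simulate_gradient()].
#' @return An [annotation_table()].
#' @export
truth_annotations <- function(truth) {
  ref <- ifelse(truth$organism == "host" &
                  truth$machinery %in% c("30S", "50S", "RNAP", "other"),
                truth$machinery, "none")
  annotation_table(truth$protein_id, truth$organism, ref)
}

default_timecourse_classes <- function() {
  data.frame(
    label = c("early_ribosome", "early_other", "mid_nvRNAP", "late_structural"),
    n     = c(8L, 21L, 5L, 6L),
    tau   = c(2, 3, 6, 9),       # onset minutes
    scale = c(1, 1, 1, 1),       # logistic scale, minutes
    # ribosome-targeting transcripts are among the most abundant early
    # mRNAs, so early classes carry larger amplitudes
    amp_multiplier = c(3, 2, 1, 1.5),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic infection time course
#'
#' Phage transcript classes accumulate along logistic curves with
#' class-specific onsets (early-ribosome at 2 min < early-other at 3 <
#' mid-nvRNAP at 6 < late-structural at 9); host transcripts are constant
#' and then decay mildly. The total phage amplitude is calibrated
#' analytically so the expected phage CDS share at 10 min equals
#' `target_share` (default 0.40) before Poisson sampling.
#'
#' @param classes Phage class table (label, n, tau, scale,
#'   amp_multiplier); onsets must be non-decreasing down the table.
#' @param timepoints Sampling times in minutes (default 0, 2, ..., 10).
#' @param n_host Number of host transcripts.
#' @param host_mean Mean host transcript expected count.
#' @param host_decay_onset,host_decay_rate Host expression is flat until
#'   `host_decay_onset` min, then decays linearly at `host_decay_rate`
#'   per min (floored at 5% of the initial level).
#' @param target_share Expected phage CDS share at the last time point
#'   (0 disables phage expression entirely).
#' @param amp_sdlog Lognormal spread of per-transcript amplitudes.
#' @param phage_transcript_ids Optional character vector of phage
#'   transcript ids, one per class member in class-table order; defaults
#'   to synthetic ids. Lets the time course share ids with
#'   [simulate_gradient()] phage proteins via [sim_gene_map()].
#' @param seed Integer seed.
#' @return A `"sim_timecourse_config"` list.
#' @export
sim_timecourse_config <- function(classes = default_timecourse_classes(),
                                  timepoints = seq(0, 10, by = 2),
                                  n_host = 600L,
                                  host_mean = 200,
                                  host_decay_onset = 2,
                                  host_decay_rate = 0.025,
                                  target_share = 0.40,
                                  amp_sdlog = 0.8,
                                  phage_transcript_ids = NULL,
                                  seed = 42L) {
  needed <- c("label", "n", "tau", "scale", "amp_multiplier")
  miss <- setdiff(needed, names(classes))
  if (length(miss))
    gs_parameter_error(sprintf("'classes' missing column(s): %s",
                               paste(miss, collapse = ", ")))
  if (any(diff(classes$tau) < 0))
    gs_parameter_error("class onsets 'tau' must be non-decreasing (early < mid < late)")
  if (target_share < 0 || target_share >= 1)
    gs_parameter_error("'target_share' must lie in [0, 1)")
  if (!is.null(phage_transcript_ids) &&
      length(phage_transcript_ids) != sum(classes$n))
    gs_parameter_error("'phage_transcript_ids' must have one id per phage transcript")
  structure(list(classes = classes, timepoints = as.numeric(timepoints),
                 n_host = as.integer(n_host), host_mean = host_mean,
                 host_decay_onset = host_decay_onset,
                 host_decay_rate = host_decay_rate,
                 target_share = target_share, amp_sdlog = amp_sdlog,
                 phage_transcript_ids = phage_transcript_ids,
                 seed = as.integer(seed)),
            class = "sim_timecourse_config")
}

host_decay_factor <- function(t, onset, rate) {
  pmax(1 - rate * pmax(t - onset, 0), 0.05)
}

#' Simulate an infection time-course count table
#'
#' @param cfg A [sim_timecourse_config()].
#' @return List with `counts` (a [counts_timecourse()]) and `truth`
#'   (data.frame: `transcript_id`, `class`, `tau`, `amplitude`).
#' @export
simulate_timecourse <- function(cfg = sim_timecourse_config()) {
  stopifnot(inherits(cfg, "sim_timecourse_config"))
  cl <- cfg$classes
  tp <- cfg$timepoints
  t_end <- tp[length(tp)]

  host_total <- cfg$n_host * cfg$host_mean
  h_end <- host_total * host_decay_factor(t_end, cfg$host_decay_onset,
                                          cfg$host_decay_rate)
  w <- cl$n * cl$amp_multiplier
  w <- w / sum(w)
  logistic_end <- plogis((t_end - cl$tau) / cl$scale)
  phage_total <- if (cfg$target_share > 0)
    (cfg$target_share / (1 - cfg$target_share)) * h_end / sum(w * logistic_end)
  else 0

  # per-transcript amplitudes: lognormal draws renormalized within class so
  # expected class totals (and hence the endpoint share) are exact
  set.seed(mix_seed(cfg$seed, 3L))
  phage_ids <- cfg$phage_transcript_ids
  if (is.null(phage_ids))
    phage_ids <- unlist(lapply(seq_len(nrow(cl)), function(k)
      sprintf("phage_tx_%s_%02d", cl$label[k], seq_len(cl$n[k]))))
  amp <- numeric(sum(cl$n)); cls <- character(sum(cl$n)); tau <- numeric(sum(cl$n))
  sc <- numeric(sum(cl$n)); pos <- 0L
  for (k in seq_len(nrow(cl))) {
    draw <- rlnorm(cl$n[k], 0, cfg$amp_sdlog)
    idx <- pos + seq_len(cl$n[k])
    amp[idx] <- phage_total * w[k] * draw / sum(draw)
    cls[idx] <- cl$label[k]; tau[idx] <- cl$tau[k]; sc[idx] <- cl$scale[k]
    pos <- pos + cl$n[k]
  }
  host_draw <- rlnorm(cfg$n_host, 0, cfg$amp_sdlog)
  host_amp <- host_total * host_draw / sum(host_draw)
  host_ids <- sprintf("host_tx_%04d", seq_len(cfg$n_host))

  lambda_phage <- outer(amp, rep(1, length(tp))) *
    plogis((matrix(tp, length(amp), length(tp), byrow = TRUE) - tau) / sc)
  lambda_host <- outer(host_amp, host_decay_factor(tp, cfg$host_decay_onset,
                                                   cfg$host_decay_rate))
  lambda <- rbind(lambda_phage, lambda_host)
  ids <- c(phage_ids, host_ids)

  counts <- matrix(0L, nrow(lambda), ncol(lambda))
  for (i in seq_len(nrow(lambda))) {
    set.seed(mix_seed(cfg$seed, 4L, i))
    counts[i, ] <- rpois(ncol(lambda), lambda[i, ])
  }
  rownames(counts) <- ids
  genome <- c(rep("phage", length(phage_ids)), rep("host", cfg$n_host))
  truth <- data.frame(transcript_id = phage_ids, class = cls, tau = tau,
                      amplitude = amp, stringsAsFactors = FALSE)
  list(counts = counts_timecourse(counts, genome, tp), truth = truth)
}

#' Protein-to-transcript map linking the two default simulations
#'
#' Maps each simulated phage protein to a transcript id `tx_<protein_id>`.
#' Use the returned `transcript_id` column as `phage_transcript_ids` in
#' [sim_timecourse_config()] (class-table order matches the default
#' gradient's phage classes: binders first as early-ribosome, free phage
#' proteins as early-other, nvRNAP-like as mid, virion as late).
#'
#' @param gradient_truth Truth data.frame from [simulate_gradient()].
#' @return `data.frame` with columns `protein_id`, `transcript_id`.
#' @export
sim_gene_map <- function(gradient_truth) {
  ph <- gradient_truth[gradient_truth$organism == "phage", , drop = FALSE]
  class_order <- c("phage_30S_binder", "phage_50S_binder", "phage_free",
                   "phage_nvRNAP", "phage_virion")
  ph <- ph[order(match(ph$class, class_order), ph$protein_id), , drop = FALSE]
  data.frame(protein_id = ph$protein_id,
             transcript_id = paste0("tx_", ph$protein_id),
             stringsAsFactors = FALSE)
}

#' Time-course configuration matched to a simulated gradient
#'
#' Builds a [sim_timecourse_config()] whose phage transcripts are the
#' transcripts of the simulated phage proteins: planted ribosome binders
#' become the early-ribosome class, remaining free phage proteins
#' early-other, nvRNAP-like proteins the mid class and virion proteins the
#' late class.
#'
#' @param gradient_truth Truth data.frame from [simulate_gradient()].
#' @param seed Integer seed.
#' @param ... Passed on to [sim_timecourse_config()].
#' @return A `"sim_timecourse_config"`.
#' @export
sim_timecourse_config_matched <- function(gradient_truth, seed = 42L, ...) {
  gm <- sim_gene_map(gradient_truth)
  ph <- gradient_truth[match(gm$protein_id, gradient_truth$protein_id), ]
  n_binder <- sum(ph$is_ribosome_binder)
  n_free <- sum(ph$class == "phage_free")
  n_mid <- sum(ph$class == "phage_nvRNAP")
  n_late <- sum(ph$class == "phage_virion")
  classes <- default_timecourse_classes()
  classes$n <- c(n_binder, n_free, n_mid, n_late)
  sim_timecourse_config(classes = classes,
                        phage_transcript_ids = gm$transcript_id,
                        seed = seed, ...)
}
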