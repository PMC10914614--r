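test_that("spike-in correction implements the median-reference formula", {
  m <- toy_intensity_matrix()   # constant spike-in -> identity
  m2 <- spike_in_normalize(m)
  expect_equal(m2$values, m$values)

  # doubling the spike-in in F05 halves every protein's F05 only
  vals <- m$values
  vals["spike", 5] <- 200
  vals[c("host_a", "phage_b"), 5] <- c(40, 8)
  m3 <- spike_in_normalize(intensity_matrix(vals, c("host", "phage", "spike_in"), "spike"))
  expect_equal(unname(m3$values["host_a", 5]), 20)
  expect_equal(unname(m3$values["phage_b", 5]), 4)
  expect_equal(m3$values[c("host_a", "phage_b"), -5],
               m$values[c("host_a", "phage_b"), -5])
})

test_that("spike-in correction inverts column-wise distortion up to one constant", {
  set.seed(11)
  clean <- matrix(runif(40 * 21, 1, 1000), 40, 21)
  clean <- rbind(clean, rep(500, 21))
  rownames(clean) <- c(sprintf("p%02d", 1:40), "spk")
  d <- exp(rnorm(21, 0, 0.5))
  distorted <- sweep(clean, 2, d, `*`)
  m <- intensity_matrix(distorted, c(rep("host", 40), "spike_in"), "spk")
  rec <- spike_in_normalize(m)$values[1:40, ]
  ratio <- rec / clean[1:40, ]
  expect_lt((max(ratio) - min(ratio)) / min(ratio), 1e-10)
})

test_that("spike-in correction is idempotent and rejects degenerate spike-ins", {
  set.seed(3)
  vals <- matrix(runif(5 * 21, 1, 100), 5, 21,
                 dimnames = list(c(sprintf("p%d", 1:4), "s"), NULL))
  m <- intensity_matrix(vals, c(rep("host", 4), "spike_in"), "s")
  once <- spike_in_normalize(m)
  twice <- spike_in_normalize(once)
  expect_lt(max(abs(twice$values - once$values)), 1e-12)
  # a zero spike-in value is caught at construction already
  vals["s", 7] <- 0
  expect_error(intensity_matrix(vals, c(rep("host", 4), "spike_in"), "s"),
               class = "gradsift_integrity_error")
})

test_that("normalize_profile matches the hand-worked examples", {
  raw <- rep(0, 21); raw[5] <- 10
  p <- normalize_profile(raw)
  expect_equal(p$fractions[5], 1)
  expect_equal(sum(p$fractions), 1)
  expect_equal(p$pellet_share, 0)
  expect_equal(p$peak_fraction, 5L)

  raw <- rep(0, 21); raw[3:5] <- c(4, 8, 4); raw[21] <- 4
  p <- normalize_profile(raw)
  expect_equal(p$fractions[3:5], c(0.5, 1, 0.5))
  expect_equal(p$pellet_share, 4 / 20)
  expect_equal(p$peak_fraction, 4L)
  expect_equal(p$total_intensity, 20)

  # gradient-only pellet denominator
  p2 <- normalize_profile(raw, pellet_denominator = "gradient_only")
  expect_equal(p2$pellet_share, 4 / 16)

  expect_error(normalize_profile(rep(0, 21)), class = "gradsift_empty_profile")
})

test_that("profile normalization invariants hold on random rows", {
  rows <- random_rows(10000, seed = 101)
  for (i in sample(nrow(rows), 500)) {   # scalar path on a subsample
    p <- normalize_profile(rows[i, ])
    if (max(rows[i, 1:20]) > 0) expect_identical(max(p$fractions), 1)
    expect_gte(p$pellet_share, 0); expect_lte(p$pellet_share, 1)
  }
  # vectorized path over all rows
  m <- intensity_matrix(`rownames<-`(rbind(rows, rep(1, 21)),
                                     c(sprintf("r%05d", seq_len(nrow(rows))), "s")),
                        c(rep("host", nrow(rows)), "spike_in"), "s")
  prof <- normalize_profiles(m)
  fm <- fraction_matrix(prof)
  has_signal <- apply(fm, 1, max) > 0
  expect_true(all(abs(apply(fm[has_signal, ], 1, max) - 1) == 0))
  expect_true(all(prof$pellet_share >= 0 & prof$pellet_share <= 1))
  # peak = smallest index attaining the maximum
  expect_identical(prof$peak_fraction[has_signal],
                   as.integer(apply(fm[has_signal, ], 1, which.max)))
})

test_that("profiles are scale invariant", {
  set.seed(5)
  for (i in 1:50) {
    raw <- runif(21, 0, 10)
    c_pos <- exp(runif(1, -8, 8))
    p1 <- normalize_profile(raw)
    p2 <- normalize_profile(c_pos * raw)
    expect_lt(max(abs(p1$fractions - p2$fractions)), 1e-12)
    expect_lt(abs(p1$pellet_share - p2$pellet_share), 1e-12)
    expect_identical(p1$peak_fraction, p2$peak_fraction)
  }
})

test_that("pellet-only rows give zero fractions and pellet share 1", {
  raw <- rep(0, 21); raw[21] <- 7
  p <- normalize_profile(raw)
  expect_identical(p$fractions, rep(0, 20))
  expect_identical(p$pellet_share, 1)
  expect_true(is.na(p$peak_fraction))
})

test_that("abundance filter applies a strict cut and spares no spike-in", {
  vals <- rbind(at_cut   = rep(10^8 / 21, 21),
                above    = rep(10^8.01 / 21, 21),
                below    = rep(10^7 / 21, 21),
                s        = rep(10^9, 21))
  m <- intensity_matrix(vals, c("host", "host", "phage", "spike_in"), "s")
  prof <- normalize_profiles(spike_in_normalize(m))
  kept <- filter_by_abundance(prof, 8.0)
  expect_identical(kept$protein_id, "above")   # 10^8 excluded: strict ">"
  all_kept <- filter_by_abundance(prof, -Inf)
  expect_setequal(all_kept$protein_id, c("at_cut", "above", "below"))
})

test_that("filter agrees with a brute-force filter over the raw table", {
  sim <- simulate_gradient(sim_gradient_config(seed = 42))
  corrected <- spike_in_normalize(sim$matrix)
  prof <- normalize_profiles(corrected)
  kept <- filter_by_abundance(prof, 8.0)
  # oracle: recompute totals directly from the corrected raw matrix
  totals <- rowSums(corrected$values)
  oracle_ids <- names(totals)[log10(totals) > 8.0 &
                                names(totals) != corrected$spike_in_id]
  expect_setequal(kept$protein_id, oracle_ids)
})

test_that("peak fraction is untouched by a constant spike-in correction", {
  m <- toy_intensity_matrix()
  before <- normalize_profiles(m)
  after <- normalize_profiles(spike_in_normalize(m))
  expect_identical(before$peak_fraction, after$peak_fraction)
})

test_that("profiles round-trip through TSV", {
  sim <- simulate_gradient(sim_gradient_config(seed = 1))
  prof <- normalize_profiles(spike_in_normalize(sim$matrix))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(prof, path)
  prof2 <- read_profiles(path)
  expect_lt(max(abs(fraction_matrix(prof2) - fraction_matrix(prof))), 1e-12)
  expect_identical(prof2$peak_fraction, prof$peak_fraction)
})
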