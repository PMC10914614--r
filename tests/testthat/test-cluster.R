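test_that("profile distance is 1 - Pearson r and behaves like a distance", {
  set.seed(21)
  p <- runif(20)
  expect_equal(profile_distance(p, p), 0)
  expect_equal(profile_distance(p, 1 - p), 2)
  for (i in 1:100) {
    a <- runif(20); b <- runif(20)
    expect_lt(abs(profile_distance(a, b) - (1 - pearson_textbook(a, b))), 1e-12)
    expect_lt(abs(profile_distance(a, b) - profile_distance(b, a)), 1e-12)
  }
  expect_error(profile_distance(rep(0.5, 20), runif(20)),
               class = "gradsift_undefined_correlation")
})

test_that("identical profiles co-cluster and k = n gives singletons", {
  X <- rbind(a = c(rep(0, 9), 1, 0.5, rep(0, 9)),
             b = c(rep(0, 9), 1, 0.5, rep(0, 9)),
             c = c(1, 0.5, rep(0, 18)))
  labels <- hierarchical_cluster(X, k = 2)
  expect_identical(labels[["a"]], labels[["b"]])
  expect_false(labels[["a"]] == labels[["c"]])
  expect_identical(unname(hierarchical_cluster(X, k = 3)), 1:3)
  expect_error(hierarchical_cluster(X, k = 4), class = "gradsift_parameter_error")
})

test_that("merge order equals exhaustive brute-force agglomeration (n <= 6)", {
  for (rep in 1:100) {
    set.seed(rep)
    n <- sample(3:6, 1)
    linkage <- sample(c("average", "complete"), 1)
    X <- matrix(runif(n * 20), n, 20,
                dimnames = list(sprintf("p%d", 1:n), NULL))
    D <- 1 - cor(t(X))
    got <- attr(hierarchical_cluster(X, k = 1, linkage = linkage), "merges")
    want <- brute_force_agglomerate(D, linkage)
    expect_identical(unname(got), unname(want))
  }
})

test_that("partitions agree with stats::hclust on tie-free data", {
  # independent route: same linkage definitions, different implementation
  set.seed(99)
  X <- matrix(runif(30 * 20), 30, 20,
              dimnames = list(sprintf("p%02d", 1:30), NULL))
  D <- as.dist(1 - cor(t(X)))
  for (linkage in c("average", "complete")) {
    for (k in c(2, 5, 9)) {
      ours <- hierarchical_cluster(X, k = k, linkage = linkage)
      ref <- cutree(hclust(D, method = linkage), k = k)
      # same partition up to label permutation: identical co-membership
      expect_identical(outer(as.integer(ours), as.integer(ours), `==`),
                       outer(as.integer(ref), as.integer(ref), `==`))
    }
  }
})

test_that("reference centroids average members and demand 3 of them", {
  X <- matrix(0, 7, 21)
  X[1:3, 10] <- 8; X[1:3, 11] <- c(4, 4, 4)
  X[4:6, 14] <- 8; X[4, 12] <- 2; X[5, 12] <- 4; X[6, 12] <- 6
  X[7, 2] <- 5
  rownames(X) <- c("s1", "s2", "s3", "l1", "l2", "l3", "free")
  m <- intensity_matrix(rbind(X, spk = rep(1, 21)),
                        c(rep("host", 7), "spike_in"), "spk")
  prof <- normalize_profiles(m)
  ann <- annotation_table(rownames(X), rep("host", 7),
                          c("30S", "30S", "30S", "50S", "50S", "50S", "none"))
  cent <- build_reference_centroids(prof, ann)
  expect_identical(sort(rownames(cent$centroids)), c("30S", "50S"))
  expect_equal(unname(cent$centroids["30S", 10]), 1)
  expect_equal(unname(cent$centroids["30S", 11]), 0.5)
  expect_equal(unname(cent$centroids["50S", 12]), mean(c(0.25, 0.5, 0.75)))
  expect_true(all(cent$centroids >= 0 & cent$centroids <= 1))

  ann2 <- annotation_table(rownames(X), rep("host", 7),
                           c("30S", "30S", "30S", "50S", "50S", "none", "RNAP"))
  expect_error(build_reference_centroids(prof, ann2),
               class = "gradsift_insufficient_reference")
})

test_that("two shifted unit peaks average to a 0.5/0.5 centroid", {
  X <- matrix(0, 3, 21)
  X[1, 10] <- 1; X[2, 12] <- 1; X[3, c(10, 12)] <- 1
  rownames(X) <- c("a", "b", "c")
  m <- intensity_matrix(rbind(X, spk = rep(1, 21)),
                        c(rep("host", 3), "spike_in"), "spk")
  prof <- normalize_profiles(m)
  # drop the third member's influence by averaging only a and b via annotation
  cent <- build_reference_centroids(
    prof, annotation_table(c("a", "b", "c"), rep("host", 3),
                           c("30S", "30S", "30S")))
  expect_equal(unname(cent$centroids["30S", 10]), 2 / 3)
  # direct two-member mean is the documented arithmetic mean
  expect_equal(unname(colMeans(fraction_matrix(prof)[c("a", "b"), ])[c(10, 12)]),
               c(0.5, 0.5))
})

test_that("centroids on the default simulation peak at the planted centers", {
  sim <- simulate_gradient(sim_gradient_config(seed = 42))
  prof <- filter_by_abundance(normalize_profiles(spike_in_normalize(sim$matrix)))
  cent <- build_reference_centroids(prof, truth_annotations(sim$truth))
  planted <- c(`30S` = 11, `50S` = 14, RNAP = 5, other = 17)
  for (lab in names(planted))
    expect_identical(unname(which.max(cent$centroids[lab, ])),
                     as.integer(planted[[lab]]))
})

test_that("assignment picks the argmax centroid and respects r_min", {
  sim <- simulate_gradient(sim_gradient_config(seed = 42))
  prof <- filter_by_abundance(normalize_profiles(spike_in_normalize(sim$matrix)))
  cent <- build_reference_centroids(prof, truth_annotations(sim$truth))
  asg <- assign_to_reference(prof, cent, r_min = 0.8)
  # a query equal to a centroid gets that label with score 1
  fraction_labels <- sprintf("F%02d", 1:20)
  fake <- prof[1:2, ]
  fake[1, fraction_labels] <- cent$centroids["50S", ]
  fake[2, fraction_labels] <- cent$centroids["RNAP", ]
  fake$protein_id <- c("q50", "qRNAP")
  asg_fake <- assign_to_reference(fake, cent, r_min = 0.8)
  expect_identical(asg_fake$label, c("50S", "RNAP"))
  expect_equal(asg_fake$score, c(1, 1))
  # anti-correlated query is unassigned
  anti <- fake[1, ]
  anti[, fraction_labels] <- 1 - cent$centroids["50S", ] / max(cent$centroids["50S", ])
  expect_identical(assign_to_reference(anti, cent, 0.8)$label, "unassigned")
  # scores are valid correlations
  expect_true(all(asg$score >= -1 & asg$score <= 1))
})

test_that("assignments recover planted machinery on the default simulation", {
  sim <- simulate_gradient(sim_gradient_config(seed = 42))
  prof <- filter_by_abundance(normalize_profiles(spike_in_normalize(sim$matrix)))
  cent <- build_reference_centroids(prof, truth_annotations(sim$truth))
  asg <- assign_to_reference(prof, cent, r_min = 0.8)
  tt <- sim$truth[match(asg$protein_id, sim$truth$protein_id), ]
  complexed <- tt$machinery %in% rownames(cent$centroids)
  accuracy <- mean(asg$label[complexed] == tt$machinery[complexed])
  expect_gte(accuracy, 0.95)
})

test_that("assignment is invariant to positive rescaling of raw intensities", {
  sim <- simulate_gradient(sim_gradient_config(seed = 7))
  m <- sim$matrix
  scaled_vals <- m$values
  host_rows <- which(m$organism == "host")[1:20]
  scaled_vals[host_rows, ] <- scaled_vals[host_rows, ] * 1e3
  m2 <- intensity_matrix(scaled_vals, m$organism, m$spike_in_id)
  p1 <- normalize_profiles(spike_in_normalize(m))
  p2 <- normalize_profiles(spike_in_normalize(m2))
  ann <- truth_annotations(sim$truth)
  c1 <- build_reference_centroids(filter_by_abundance(p1, -Inf), ann)
  c2 <- build_reference_centroids(filter_by_abundance(p2, -Inf), ann)
  a1 <- assign_to_reference(filter_by_abundance(p1, -Inf), c1)
  a2 <- assign_to_reference(filter_by_abundance(p2, -Inf), c2)
  expect_identical(a1$label, a2$label)
  expect_lt(max(abs(a1$score - a2$score)), 1e-9)
})
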