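test_that("correlation matrix matches the textbook formula", {
  # identical profiles correlate at 1; reversed profiles at -1 (raw counts)
  counts <- cbind(S1 = c(1, 2, 3), S2 = c(1, 2, 3), S3 = c(3, 2, 1),
                  S4 = c(1, 3, 2))
  rownames(counts) <- paste0("P", 1:3)
  cm <- make_cm(counts, groups = c("CN", "CN", "CR", "CR"))
  cc <- correlation_matrix(cm, transform = "none")
  expect_equal(cc["S1", "S2"], 1)
  expect_equal(cc["S1", "S3"], -1)

  # random matrix against a direct covariance-formula oracle
  set.seed(101)
  big <- make_cm(matrix(rpois(1600, 20), 200, 8))
  cc <- correlation_matrix(big, transform = "none")
  x <- big$counts
  for (i in 1:7) for (j in (i + 1):8) {
    xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
    expect_equal(cc[i, j], sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2)),
                 tolerance = 1e-12)
  }
  expect_identical(unclass(cc), t(unclass(cc)))
  expect_equal(unname(diag(cc)), rep(1, 8))

  # depth-normalized transform is invariant to a pure depth rescale
  dbl <- big
  dbl$counts[, 1] <- dbl$counts[, 1] * 4L
  cm2 <- make_cm(dbl$counts)
  c1 <- correlation_matrix(big)
  c2 <- correlation_matrix(cm2)
  expect_equal(c1["S1", "S2"], c2["S1", "S2"], tolerance = 0.02)

  flat <- make_cm(cbind(S1 = c(2L, 2L), S2 = c(1L, 5L)),
                  groups = c("CN", "CR"))
  expect_error(correlation_matrix(flat, transform = "none"), "S1")
})

test_that("combined pseudo-samples are pooled group counts", {
  set.seed(103)
  cm <- make_cm(matrix(rpois(80, 10), 10, 8))
  cc <- correlation_matrix(cm, include_combined = TRUE)
  expect_true(all(c("CN_combined", "CR_combined") %in% rownames(cc)))
  expect_equal(dim(cc), c(10, 10))
})

test_that("agglomerative clustering reproduces hand-computed trees", {
  # two samples merge at their distance
  d2 <- matrix(c(1, 0.6, 0.6, 1), 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  tree <- cluster_samples(d2)
  expect_equal(tree$height, 0.4)
  expect_equal(sort(tree$labels[-tree$merge[1, ]]), c("A", "B"))

  # two tight pairs: topology ((A,B),(C,D)) under average linkage
  sim <- matrix(0.1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  sim[1, 2] <- sim[2, 1] <- 0.9
  sim[3, 4] <- sim[4, 3] <- 0.9
  diag(sim) <- 1
  tree <- cluster_samples(sim)
  phy <- ape::read.tree(text = to_newick(tree))
  pairs <- ape::prop.part(phy)
  tip_sets <- lapply(pairs, function(i) sort(attr(pairs, "labels")[i]))
  expect_true(any(vapply(tip_sets, identical, TRUE, c("A", "B"))))
  expect_true(any(vapply(tip_sets, identical, TRUE, c("C", "D"))))

  # planted 4+4 structure is recovered as two disjoint subtrees,
  # and the topology is invariant under uniform distance scaling
  set.seed(111)
  base <- matrix(runif(64, 0, 0.05), 8, 8)
  base <- (base + t(base)) / 2
  base[1:4, 5:8] <- base[1:4, 5:8] + 0.7
  base[5:8, 1:4] <- t(base[1:4, 5:8])
  diag(base) <- 0
  ids <- c(paste0("CN", 1:4), paste0("CR", 1:4))
  dimnames(base) <- list(ids, ids)
  corr <- 1 - base
  tree <- cluster_samples(corr)
  phy <- ape::read.tree(text = to_newick(tree))
  parts <- ape::prop.part(phy)
  tip_sets <- lapply(parts, function(i) sort(attr(parts, "labels")[i]))
  expect_true(any(vapply(tip_sets, identical, TRUE, sort(ids[1:4]))) ||
              any(vapply(tip_sets, identical, TRUE, sort(ids[5:8]))))
  scaled <- 1 - 3 * base
  expect_equal(cluster_samples(scaled)$merge, tree$merge)
})

test_that("equal-distance merges break ties lexicographically", {
  ids <- c("b", "a", "c")
  sim <- matrix(0.5, 3, 3, dimnames = list(ids, ids))
  diag(sim) <- 1                      # all pairwise distances equal
  tree <- cluster_samples(sim)
  first <- sort(tree$labels[-tree$merge[1, ]])
  expect_identical(first, c("a", "b"))
})

test_that("Newick serialization is exact and parser-compatible", {
  d2 <- matrix(c(1, 0.6, 0.6, 1), 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_identical(to_newick(cluster_samples(d2)), "(A:0.2,B:0.2);")

  # leaf names with spaces are underscored
  dimnames(d2) <- list(c("CN 1", "CR 1"), c("CN 1", "CR 1"))
  expect_identical(to_newick(cluster_samples(d2)), "(CN_1:0.2,CR_1:0.2);")

  # round-trip through the independent ape parser preserves the tree
  set.seed(121)
  cm <- make_cm(matrix(rpois(400, 15), 50, 8))
  tree <- cluster_samples(correlation_matrix(cm))
  nwk <- to_newick(tree, digits = 12)
  phy <- ape::read.tree(text = nwk)
  orig <- ape::as.phylo(tree)
  expect_true(ape::all.equal.phylo(phy, orig, use.edge.length = FALSE))
  expect_equal(sort(phy$edge.length), sort(orig$edge.length),
               tolerance = 1e-9)
})

test_that("overlap counts reflect detection strata", {
  # every protein everywhere
  full <- make_cm(matrix(3L, 5, 8))
  ov <- overlap_counts(full)
  expect_equal(ov$per_group$CN$in_all_samples, 5)
  expect_equal(ov$intersection, 5)
  expect_equal(ov$only_ref, 0)

  # planted strata: 3 in all CN, 2 in some CN only, 2 CR-only, 1 absent
  counts <- matrix(0L, 8, 8)
  counts[1:3, 1:4] <- 1L                       # all CN samples
  counts[4:5, 1] <- 1L                         # one CN sample
  counts[6:7, 5:8] <- 1L                       # CR only
  cm <- make_cm(counts)
  ov <- overlap_counts(cm)
  expect_equal(ov$per_group$CN$detected, 5)
  expect_equal(ov$per_group$CN$in_all_samples, 3)
  expect_equal(ov$per_group$CR$detected, 2)
  expect_equal(ov$intersection, 0)
  expect_equal(ov$only_ref, 5)
  expect_equal(ov$only_cmp, 2)
})
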