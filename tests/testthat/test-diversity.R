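# Bray-Curtis, PCoA, PERMANOVA and hierarchical clustering, checked against
# hand results, brute-force oracles and the vegan/ape/stats reference
# implementations.

test_that("Bray-Curtis matches hand values and the definition", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)   # disjoint support
  expect_equal(bray_curtis(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  # on normalized profiles BC is half the L1 distance
  set.seed(5)
  for (i in 1:50) {
    x <- random_profile(6)
    y <- random_profile(6)
    expect_equal(bray_curtis(x, y), 0.5 * sum(abs(x - y)), tolerance = 1e-15)
    expect_equal(bray_curtis(x, y), bray_curtis(y, x))
  }
})

test_that("Bray-Curtis agrees with vegan::vegdist", {
  skip_if_not_installed("vegan")
  set.seed(9)
  profiles <- matrix(rgamma(8 * 10, 1), nrow = 8,
                     dimnames = list(paste0("t", 1:8), paste0("s", 1:10)))
  ours <- bray_curtis_matrix(profiles)
  ref <- as.matrix(vegan::vegdist(t(profiles), method = "bray"))
  expect_equal(unclass(ours), ref[rownames(ours), colnames(ours)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("distance_matrix validates symmetry, diagonal and range", {
  m <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_s3_class(distance_matrix(m), "distance_matrix")
  bad <- m; bad[1, 2] <- 0.7
  expect_error(distance_matrix(bad), "symmetric")
  bad2 <- m; diag(bad2) <- 0.1
  expect_error(distance_matrix(bad2), "diagonal")
})

test_that("PCoA reproduces forced geometries", {
  # two samples at distance d sit at +/- d/2 on the single axis
  d <- distance_matrix(matrix(c(0, 0.8, 0.8, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  res <- pcoa(d, n_axes = 1)
  expect_equal(sort(res$coordinates[, 1]), c(-0.4, 0.4), ignore_attr = TRUE)
  # three equidistant samples: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  res3 <- pcoa(distance_matrix(d3), n_axes = 2)
  pos <- res3$eigenvalues[res3$eigenvalues > 1e-12]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-12)
})

test_that("PCoA of Euclidean distances is exact and matches cmdscale", {
  set.seed(13)
  for (i in 1:5) {
    n <- sample(5:20, 1)
    pts <- cbind(runif(n), runif(n))
    rownames(pts) <- paste0("s", 1:n)
    d <- distance_matrix(as.matrix(dist(pts)))
    res <- pcoa(d, n_axes = 2)
    emb <- as.matrix(dist(res$coordinates))
    expect_lt(max(abs(emb - unclass(d))), 1e-8)
    ref <- stats::cmdscale(unclass(d), k = 2)
    expect_equal(abs(res$coordinates), abs(ref), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("PCoA asks for no more axes than samples allow and reports
           negative eigenvalues", {
  d <- random_euclidean_dist(5, seed = 3)
  expect_error(pcoa(d, n_axes = 5), "n_axes")
  expect_message(res <- pcoa(d, n_axes = 4), "positive eigenvalue")
  expect_lte(ncol(res$coordinates), 4)
  expect_lte(sum(res$proportion_explained), 1 + 1e-12)
})

test_that("PCoA is permutation-equivariant", {
  d <- random_euclidean_dist(8, seed = 21)
  res <- pcoa(d, 2)
  perm <- sample(8)
  dp <- distance_matrix(unclass(d)[perm, perm])
  resp <- pcoa(dp, 2)
  expect_equal(resp$coordinates[rownames(d), ], res$coordinates,
               tolerance = 1e-9)
})

test_that("PERMANOVA reproduces degenerate and structureless geometries", {
  # two tight clusters: all between-group variance
  m <- matrix(1, 4, 4); m[1:2, 1:2] <- 0; m[3:4, 3:4] <- 0; diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:4), paste0("s", 1:4))
  res <- permanova(distance_matrix(m), c("A", "A", "B", "B"), 99, seed = 1)
  expect_equal(res$R2, 1)
  # equal distances everywhere: R2 equals the no-structure expectation
  n <- 9
  eq <- matrix(1, n, n); diag(eq) <- 0
  dimnames(eq) <- list(paste0("s", 1:n), paste0("s", 1:n))
  groups <- rep(c("A", "B", "C"), each = 3)
  res_eq <- permanova(distance_matrix(eq), groups, 9, seed = 1)
  expect_equal(res_eq$R2, (3 - 1) / (n - 1), tolerance = 1e-12)
})

test_that("pseudo-F matches vegan::adonis2 on random instances", {
  skip_if_not_installed("vegan")
  for (s in 1:4) {
    n <- 8 + s
    d <- random_euclidean_dist(n, seed = 100 + s)
    groups <- rep_len(c("A", "B", "C"), n)
    ours <- permanova(d, groups, 19, seed = 1)
    ref <- vegan::adonis2(stats::as.dist(unclass(d)) ~ g,
                          data = data.frame(g = groups), permutations = 19)
    expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
    expect_equal(ours$R2, ref$R2[1], tolerance = 1e-10)
  }
})

test_that("exhaustive enumeration matches the brute-force oracle exactly", {
  d <- random_euclidean_dist(4, seed = 7)
  groups <- c("A", "A", "B", "B")
  res <- permanova(d, groups, 999, seed = 1)
  expect_true(res$exhaustive)
  expect_identical(res$n_permutations, 6L) # 4!/(2!2!) arrangements
  expect_equal(res$pseudo_F, brute_pseudo_f(unclass(d), groups),
               tolerance = 1e-12)
  expect_identical(res$p_value, brute_exhaustive_p(unclass(d), groups))

  # three groups, uneven sizes
  d2 <- random_euclidean_dist(6, seed = 8)
  g2 <- c("A", "A", "A", "B", "B", "C")
  res2 <- permanova(d2, g2, 999, seed = 1)
  expect_true(res2$exhaustive)
  expect_equal(res2$p_value, brute_exhaustive_p(unclass(d2), g2))
})

test_that("Monte Carlo p-values converge to the exhaustive answer", {
  d <- random_euclidean_dist(8, seed = 31)
  groups <- rep(c("A", "B"), each = 4) # 70 distinct arrangements
  exact <- permanova(d, groups, 999, seed = 1)
  expect_true(exact$exhaustive)
  mc <- permanova(d, groups, 63, seed = 5) # 70 > 63 + 1 forces Monte Carlo
  expect_false(mc$exhaustive)
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 63)
  expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 2 / 64)
  # seeded determinism
  expect_identical(mc$p_value, permanova(d, groups, 63, seed = 5)$p_value)
})

test_that("hierarchical clustering follows the hand-simulated merges", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d <- distance_matrix(m)
  tree <- hierarchical_cluster(d, "complete")
  expect_equal(tree$height, c(1, 3)) # merge (A,B) at 1, then C at max(2,3)
  expect_identical(sort(tree$labels[-tree$merge[1, ]]), c("A", "B"))
  avg <- hierarchical_cluster(d, "average")
  expect_identical(avg$merge[1, ], tree$merge[1, ]) # same first merge
  expect_equal(avg$height, c(1, 2.5))               # heights differ
  single <- hierarchical_cluster(d, "single")
  expect_equal(single$height, c(1, 2))

  # identical samples merge at height zero
  z <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(hierarchical_cluster(distance_matrix(z))$height, 0)
})

test_that("clustering agrees with stats::hclust on tie-free matrices", {
  for (s in 1:3) {
    d <- random_euclidean_dist(10, seed = 200 + s)
    for (linkage in c("complete", "average", "single")) {
      ours <- hierarchical_cluster(d, linkage)
      ref <- stats::hclust(stats::as.dist(unclass(d)), method = linkage)
      co_ours <- as.matrix(stats::cophenetic(ours))
      co_ref <- as.matrix(stats::cophenetic(ref))
      expect_equal(co_ours[rownames(co_ref), colnames(co_ref)], co_ref,
                   tolerance = 1e-12)
    }
  }
})

test_that("tied merge distances resolve by lexicographic member id", {
  # B-C and A-D both at distance 1: pair containing A merges first
  m <- matrix(2, 4, 4)
  dimnames(m) <- list(c("B", "C", "A", "D"), c("B", "C", "A", "D"))
  m["B", "C"] <- m["C", "B"] <- 1
  m["A", "D"] <- m["D", "A"] <- 1
  diag(m) <- 0
  tree <- hierarchical_cluster(distance_matrix(m))
  first <- sort(tree$labels[-tree$merge[1, ]])
  expect_identical(first, c("A", "D"))
})

test_that("Newick export round-trips through ape with doubled heights", {
  skip_if_not_installed("ape")
  d <- random_euclidean_dist(7, seed = 55)
  tree <- hierarchical_cluster(d, "complete")
  nwk <- as_newick(tree)
  expect_match(nwk, ";$")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(d))
  co_phy <- ape::cophenetic.phylo(phy)
  co_ours <- as.matrix(stats::cophenetic(tree))
  # ultrametric tree: leaf-to-leaf path length is twice the merge height
  expect_equal(co_phy[rownames(co_ours), colnames(co_ours)], 2 * co_ours,
               tolerance = 1e-6)
})

test_that("diversity_analysis wires profiles, groupings and outputs together", {
  cfg <- small_study_config(seed = 61L)
  study <- generate_study(cfg)
  div <- diversity_analysis(study$tables, study$metadata,
                            n_permutations = 49, seed = 9)
  expect_identical(ncol(div$profiles), 48L) # 8 tables x 6 spiked samples
  expect_equal(unname(colSums(div$profiles)), rep(1, 48), tolerance = 1e-12)
  expect_setequal(unique(div$groups$library_type), c("DNA", "RNA"))
  expect_s3_class(div$permanova$library_type, "permanova_result")
  expect_gt(div$permanova$library_type$R2, 0)
  expect_match(div$newick, ";$")
  withctrl <- diversity_analysis(study$tables, study$metadata,
                                 include_controls = TRUE,
                                 n_permutations = 9, seed = 9)
  expect_identical(ncol(withctrl$profiles), 72L)
})
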