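test_that("clustering separates clean blocks and reproduces ultrametrics", {
  d <- two_block_dissimilarity()
  dend <- hierarchical_cluster(d)
  expect_s3_class(dend, "hclust")
  # blocks merge at 0, the two blocks join at 1
  expect_equal(sort(dend$height)[1:8], rep(0, 8))
  expect_equal(max(dend$height), 1)

  # three equidistant points: final merge at the common distance
  d3 <- matrix(0.4, 3, 3); diag(d3) <- 0
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  expect_equal(max(hierarchical_cluster(d3)$height), 0.4)

  # an ultrametric is reproduced exactly by cophenetic distances
  set.seed(21)
  base <- hierarchical_cluster(two_block_dissimilarity())
  um <- as.matrix(stats::cophenetic(base))
  dend2 <- hierarchical_cluster(um)
  expect_equal(as.matrix(stats::cophenetic(dend2)), um)

  expect_error(hierarchical_cluster(matrix(0, 1, 1)), "at least 2")
})

test_that("static cut prunes small clusters to grey", {
  d <- two_block_dissimilarity()
  dend <- hierarchical_cluster(d)
  lab <- cut_modules(dend, cut_height = 0.5, min_module_size = 3)
  expect_equal(length(unique(lab)), 2L)
  expect_false("grey" %in% lab)
  expect_equal(unname(table(lab)), array(c(5L, 5L)), ignore_attr = TRUE)

  # a 2-leaf block below min size becomes grey
  d2 <- matrix(1, 7, 7)
  d2[1:5, 1:5] <- 0; d2[6:7, 6:7] <- 0; diag(d2) <- 0
  dimnames(d2) <- list(paste0("f", 1:7), paste0("f", 1:7))
  lab2 <- cut_modules(hierarchical_cluster(d2), cut_height = 0.5,
                      min_module_size = 3)
  expect_equal(sum(lab2 == "grey"), 2L)
  expect_equal(sum(lab2 != "grey"), 5L)

  # cutting above the final merge yields a single all-inclusive module
  lab3 <- cut_modules(dend, cut_height = 1.5, min_module_size = 3)
  expect_equal(length(unique(lab3)), 1L)
  expect_false("grey" %in% lab3)

  # all-grey outcome warns but is valid
  expect_warning(
    labg <- cut_modules(dend, cut_height = 0.5, min_module_size = 6),
    "grey")
  expect_true(all(labg == "grey"))
})

test_that("lowering the cut height only refines the partition", {
  sim <- generate_synthetic(synthetic_spec(), seed = 17)
  d <- dissimilarity(topological_overlap(
    adjacency(correlation_matrix(autoscale(sim$abundance)))))
  dend <- hierarchical_cluster(d)
  hmax <- max(dend$height)
  prev <- stats::cutree(dend, h = hmax * 0.99)
  for (f in c(0.9, 0.8, 0.6)) {
    cur <- stats::cutree(dend, h = hmax * f)
    # every current cluster lies within one previous cluster
    expect_true(all(tapply(prev, cur, function(v) length(unique(v))) == 1L))
    prev <- cur
  }
})

test_that("hybrid cut rescues grey features with strong module overlap", {
  sim <- generate_synthetic(synthetic_spec(), seed = 23)
  x <- autoscale(sim$abundance)
  w <- topological_overlap(adjacency(correlation_matrix(x)))
  dend <- hierarchical_cluster(dissimilarity(w))
  # force a low cut that greys out some block members
  h <- 0.35 * max(dend$height)
  static <- suppressWarnings(cut_modules(dend, cut_height = h,
                                         min_module_size = 5))
  hybrid <- suppressWarnings(cut_modules(dend, cut_height = h,
                                         min_module_size = 5,
                                         method = "hybrid", tom = w,
                                         rescue_threshold = 0.1))
  expect_lte(sum(hybrid == "grey"), sum(static == "grey"))
  # non-grey static assignments are never overridden
  kept <- static != "grey"
  expect_identical(hybrid[kept], static[kept])
  expect_error(cut_modules(dend, method = "hybrid"),
               "requires the topological")
})

test_that("modules are renamed by size along the conventional palette", {
  lab <- c(rep("5", 13), rep("2", 12), rep("9", 6), rep("grey", 15))
  names(lab) <- paste0("f", seq_along(lab))
  colors <- assign_colors(lab)
  expect_equal(unname(colors[1]), "turquoise")   # size 13
  expect_equal(unname(colors[14]), "blue")       # size 12
  expect_equal(unname(colors[26]), "brown")      # size 6
  expect_equal(sum(colors == "grey"), 15L)
  # partition property: sizes sum to the total
  expect_equal(sum(table(colors)), length(lab))

  # ties broken by first-feature order
  tie <- c(rep("b", 3), rep("a", 3))
  names(tie) <- paste0("f", 1:6)
  ct <- assign_colors(tie)
  expect_equal(unname(ct[1]), "turquoise")
  expect_equal(unname(ct[4]), "blue")

  # single module and no-module cases
  one <- stats::setNames(rep("1", 4), paste0("f", 1:4))
  expect_true(all(assign_colors(one) == "turquoise"))
  none <- stats::setNames(rep("grey", 4), paste0("f", 1:4))
  expect_identical(assign_colors(none), none)

  # palette override
  expect_equal(unname(assign_colors(one, palette = c("salmon"))[1]), "salmon")
})

test_that("planted blocks without effects are recovered (ARI >= 0.9, 20 seeds)", {
  spec <- synthetic_spec(effect_size = 0)  # rho_between = 0 exactly
  ari <- vapply(1:20, function(s) {
    sim <- generate_synthetic(spec, seed = s)
    d <- dissimilarity(topological_overlap(
      adjacency(correlation_matrix(autoscale(sim$abundance)))))
    colors <- assign_colors(suppressWarnings(cut_modules(
      hierarchical_cluster(d))))
    adjusted_rand_index(colors, sim$truth)
  }, numeric(1))
  expect_gte(mean(ari), 0.9)
})

test_that("dendrogram exports are well-formed", {
  dend <- hierarchical_cluster(two_block_dissimilarity())
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(dend, nwk)
  tree <- ape::read.tree(nwk)
  expect_equal(sort(tree$tip.label), sort(dend$labels))

  mtsv <- withr::local_tempfile(fileext = ".tsv")
  write_dendrogram_merges(dend, mtsv)
  mt <- read.delim(mtsv)
  expect_equal(nrow(mt), 9L)  # n - 1 merges
  expect_equal(mt$height, dend$height)

  atsv <- withr::local_tempfile(fileext = ".tsv")
  colors <- stats::setNames(rep(c("turquoise", "grey"), 5), dend$labels)
  write_module_assignment(colors, atsv)
  back <- read.delim(atsv)
  expect_equal(back$module, unname(colors[back$feature]))
})

test_that("adjusted Rand index behaves as a chance-corrected agreement", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  perm <- c("x", "y", "z")[a]
  expect_equal(adjusted_rand_index(a, perm), 1)
  set.seed(99)
  b <- sample(a)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.25)
})
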