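test_that("pca reproduces known spectra and reconstructs the data", {
  # construct data whose sample covariance is exactly [[2,1],[1,2]]
  # (eigenvalues 3 and 1 -> variance fractions 0.75/0.25) from orthonormal
  # centered columns, independently of the pca() implementation
  z <- cbind(c(1, -1, 1, -1) / 2, c(1, 1, -1, -1) / 2)
  S <- matrix(c(2, 1, 1, 2), 2, 2)
  x <- z %*% chol(3 * S)   # t(x) %*% x / (n-1) == S
  dimnames(x) <- list(paste0("s", 1:4), c("f1", "f2"))
  p <- pca(x)
  expect_equal(p$variance_explained, c(0.75, 0.25), tolerance = 1e-12)

  # rank-1 matrix: all variance on the first component
  r1 <- outer(c(1, 2, 3, 4), c(1, -2))
  dimnames(r1) <- list(paste0("s", 1:4), c("f1", "f2"))
  expect_equal(pca(r1)$variance_explained[1], 1, tolerance = 1e-12)

  # full-rank case: fractions sum to 1 and scores x loadings' recovers the
  # centered input
  set.seed(51)
  x <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("f", 1:6)))
  p <- pca(x)
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  recon <- p$scores %*% t(p$loadings)
  centered <- sweep(x, 2, colMeans(x))
  expect_lt(max(abs(recon - centered)), 1e-9)
  # orthonormal loadings, deterministic sign
  expect_equal(crossprod(p$loadings), diag(6), tolerance = 1e-12,
               ignore_attr = TRUE)
  for (j in 1:6) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)

  expect_error(pca(matrix(3, 4, 3)), "no variance")
})

test_that("top_loadings filters by direction thresholds", {
  p <- structure(list(loadings = matrix(c(0.25, 0.05, -0.15), 3, 1,
                                        dimnames = list(c("f1", "f2", "f3"),
                                                        "PC1"))),
                 class = "wmcna_pca")
  sel <- top_loadings(p, 1, pos_threshold = 0.20, neg_threshold = -0.10)
  expect_equal(sel$feature, c("f1", "f3"))
  expect_equal(sel$direction, c("+", "-"))

  expect_equal(nrow(top_loadings(p, 1, 0.5, -0.5)), 0L)
  all_sel <- top_loadings(p, 1, 0, 0)  # thresholds (0, 0) select everything
  expect_equal(sort(all_sel$feature), c("f1", "f2", "f3"))
})

test_that("blsom collocates identical profiles and separates clean clusters", {
  set.seed(61)
  base <- matrix(rnorm(120), 12, 10,
                 dimnames = list(paste0("s", 1:12), paste0("f", 1:10)))
  x <- cbind(base, f_dup = base[, 1])
  som <- blsom_fit(x, rows = 3, cols = 3, epochs = 30)
  expect_equal(unname(som$assignment["f_dup"]), unname(som$assignment["f1"]))

  # two well-separated feature clusters on a 1x2 lattice: one per cell
  up <- rep(c(2, -2), each = 6)
  x2 <- cbind(a1 = up + rnorm(12, sd = 0.1), a2 = up + rnorm(12, sd = 0.1),
              b1 = -up + rnorm(12, sd = 0.1), b2 = -up + rnorm(12, sd = 0.1))
  rownames(x2) <- paste0("s", 1:12)
  som2 <- blsom_fit(x2, rows = 1, cols = 2, epochs = 30)
  asg <- som2$assignment
  expect_equal(asg[["a1"]], asg[["a2"]])
  expect_equal(asg[["b1"]], asg[["b2"]])
  expect_false(asg[["a1"]] == asg[["b1"]])

  # determinism: identical fit on re-run
  som3 <- blsom_fit(x2, rows = 1, cols = 2, epochs = 30)
  expect_identical(som2$codes, som3$codes)
  expect_identical(som2$assignment, som3$assignment)

  expect_warning(blsom_fit(x2, rows = 4, cols = 4, epochs = 5), "lattice")
})

test_that("blsom keeps planted blocks in compact lattice neighborhoods", {
  # structured toy: 3 tight blocks (rho = 0.9), 3x3 lattice
  spec <- synthetic_spec(rho_within = 0.9, n_background = 0, effect_size = 0)
  frac <- vapply(1:20, function(s) {
    sim <- generate_synthetic(spec, seed = 300 + s)
    x <- autoscale(sim$abundance)
    som <- blsom_fit(x, rows = 3, cols = 3)
    cell <- som$cell_of
    ok <- 0; tot <- 0
    for (b in paste0("block", 1:3)) {
      members <- names(sim$truth)[sim$truth == b]
      rc <- cell[match(members, cell$feature), c("row", "col")]
      cells <- paste(rc$row, rc$col)
      modal <- rc[which(cells == names(sort(table(cells),
                                            decreasing = TRUE))[1])[1], ]
      cheb <- pmax(abs(rc$row - modal$row), abs(rc$col - modal$col))
      ok <- ok + sum(cheb <= 1); tot <- tot + length(members)
    }
    ok / tot
  }, numeric(1))
  expect_gte(mean(frac), 0.9)
})

test_that("blsom_compare categorizes cells by the +/- 1 SD rule", {
  # features with known population SD; one sample pushed by a known amount
  n <- 10
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:4)))
  x <- scale(x)  # unit sample SD per feature
  pop_sd <- apply(x, 2, sd) * sqrt((n - 1) / n)
  mu <- colMeans(x)
  x["s1", ] <- mu + c(1.5, 0.5, -0.5, -1.5) * pop_sd
  som <- blsom_fit(x, rows = 2, cols = 2, epochs = 20)
  cmp <- blsom_compare(som, x, left = "s1", right = "population")
  # appending a sample equal to the column means leaves those means
  # unchanged, so that sample is all-neutral against the population
  xz <- rbind(x, s_mean = colMeans(x))
  somz <- blsom_fit(xz, rows = 2, cols = 2, epochs = 20)
  cz <- blsom_compare(somz, xz, left = "s_mean", right = "population")
  expect_true(all(cz$category == "neutral"))

  # category of a singleton cell follows its member's deviation
  for (f in colnames(x)) {
    cell <- som$assignment[[f]]
    members <- names(som$assignment)[som$assignment == cell]
    if (length(members) > 1L) next
    dev <- (x["s1", f] - mean(x[, f])) / (sd(x[, f]) * sqrt((n - 1) / n))
    want <- if (dev > 1) "strong_up" else if (dev > 0) "weak_up"
            else if (dev == 0) "neutral" else if (dev >= -1) "weak_down"
            else "strong_down"
    expect_equal(cmp$category[cmp$cell == cell], want)
  }

  # antisymmetry: swapping sides mirrors the categories
  cab <- blsom_compare(som, x, left = "s1", right = "s3")
  cba <- blsom_compare(som, x, left = "s3", right = "s1")
  flip <- c(strong_up = "strong_down", weak_up = "weak_down",
            neutral = "neutral", weak_down = "weak_up",
            strong_down = "strong_up")
  expect_equal(unname(flip[cab$category]), cba$category)

  expect_error(blsom_compare(som, x, left = "nope"), "unknown sample")
})
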