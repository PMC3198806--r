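#' Principal component analysis of a scaled abundance matrix
#'
#' Singular value decomposition of the column-centered matrix. Scores are the
#' sample coordinates (U D), loadings the feature weights (V, orthonormal),
#' and `variance_explained` the per-component fraction of total variance.
#' Signs follow a deterministic convention: the largest-magnitude loading of
#' each component is positive.
#'
#' @param x samples x features numeric matrix (typically autoscaled).
#' @param n_components number of components to keep (default all).
#' @return list of class `wmcna_pca`: `scores`, `loadings`,
#'   `variance_explained`, `center`.
#' @export
pca <- function(x, n_components = NULL) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, ncol(x) >= 2L)
  center <- colMeans(x)
  xc <- sweep(x, 2L, center, "-")
  if (all(xc == 0)) stop("matrix has no variance; PCA undefined")
  sv <- svd(xc)
  pos <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[pos]
  u <- sv$u[, pos, drop = FALSE]
  v <- sv$v[, pos, drop = FALSE]
  k <- min(n_components %||% length(d), length(d))
  varexp <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  u <- u[, seq_len(k), drop = FALSE]
  v <- v[, seq_len(k), drop = FALSE]
  d <- d[seq_len(k)]
  for (j in seq_len(k)) {          # deterministic sign convention
    if (v[which.max(abs(v[, j])), j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  scores <- sweep(u, 2L, d, "*")
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(v) <- list(colnames(x), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = v,
                 variance_explained = varexp, center = center),
            class = "wmcna_pca")
}

#' Screen PCA loadings by thresholds
#'
#' Returns the features whose loading on one component exceeds a positive
#' threshold or falls below a negative one, labeled by direction — the usual
#' way a component is annotated with its dominant metabolites.
#'
#' @param p `wmcna_pca` object.
#' @param component component index (1-based).
#' @param pos_threshold loading value above which a feature is reported `"+"`.
#' @param neg_threshold loading value below which a feature is reported `"-"`.
#' @return data.frame with columns `feature`, `loading`, `direction`, ordered
#'   by decreasing |loading|.
#' @export
top_loadings <- function(p, component = 1L, pos_threshold = 0.20,
                         neg_threshold = -0.20) {
  stopifnot(inherits(p, "wmcna_pca"), is.finite(pos_threshold),
            is.finite(neg_threshold))
  l <- p$loadings[, component]
  sel <- l > pos_threshold | l < neg_threshold
  out <- data.frame(feature = names(l)[sel], loading = unname(l[sel]),
                    direction = ifelse(l[sel] > 0, "+", "-"),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$loading)), , drop = FALSE]
}

#' Fit a batch-learning self-organizing map of metabolite profiles
#'
#' Places features (metabolites) on a 2-D lattice so that features with
#' similar abundance profiles across samples occupy the same or adjacent
#' cells. Each feature is a vector over samples. Batch learning: each epoch
#' assigns every feature to its nearest reference vector (Euclidean), then
#' replaces every reference vector with the neighborhood-kernel-weighted mean
#' of the assigned features; a Gaussian kernel on lattice distance with a
#' radius shrinking linearly to zero makes the final epochs plain batch
#' k-means on the lattice. Reference vectors are initialized on the plane
#' spanned by the first two principal components of the feature cloud, so the
#' fit is deterministic given the data; `seed` only perturbs initialization
#' when `jitter > 0`.
#'
#' @param x scaled samples x features matrix; features are mapped.
#' @param rows,cols lattice dimensions; default a near-square lattice with
#'   about `5 * sqrt(n_features)` cells, the usual SOM sizing heuristic.
#' @param epochs batch iterations (default 100).
#' @param radius initial neighborhood radius in lattice units; default half
#'   the larger lattice dimension.
#' @param jitter sd of optional Gaussian noise added to the initial reference
#'   vectors (default 0 = fully deterministic).
#' @param seed RNG seed used only when `jitter > 0`.
#' @return list of class `wmcna_som`: `rows`, `cols`, `codes` (cells x
#'   samples reference vectors), `assignment` (feature -> cell index),
#'   `cell_of` (data.frame feature, row, col).
#' @export
blsom_fit <- function(x, rows = NULL, cols = NULL, epochs = 100,
                      radius = NULL, jitter = 0, seed = 1) {
  stopifnot(is.matrix(x))
  feats <- t(x)                       # features x samples
  n_feat <- nrow(feats)
  if (is.null(rows) || is.null(cols)) {
    side <- max(2L, ceiling(sqrt(5 * sqrt(n_feat))))
    rows <- rows %||% side
    cols <- cols %||% side
  }
  n_cells <- rows * cols
  if (n_cells < 2L) stop("lattice needs at least 2 cells")
  if (n_cells > 2L * n_feat)
    warning("lattice has more than twice as many cells as features")
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  # init: span the first two PC axes of the feature cloud
  pc <- pca(feats, n_components = 2L)
  s1 <- pc$scores[, 1L]
  s2 <- if (ncol(pc$scores) >= 2L) pc$scores[, 2L] else rep(0, n_feat)
  ax1 <- seq(min(s1), max(s1), length.out = cols)[grid$col]
  ax2 <- seq(min(s2), max(s2), length.out = rows)[grid$row]
  v <- pc$loadings
  codes <- matrix(rep(colMeans(feats), each = n_cells), n_cells, ncol(feats))
  codes <- codes + outer(ax1, v[, 1L])
  if (ncol(v) >= 2L) codes <- codes + outer(ax2, v[, 2L])
  if (jitter > 0) {
    codes <- codes + with_seed(seed, matrix(
      stats::rnorm(length(codes), sd = jitter), nrow(codes)))
  }
  radius <- radius %||% (max(rows, cols) / 2)
  lattice_d2 <- as.matrix(stats::dist(grid))^2
  for (ep in seq_len(epochs)) {
    r_ep <- radius * (1 - (ep - 1) / epochs)   # shrink linearly to 0
    d2 <- cross_dist2(feats, codes)
    bmu <- max.col(-d2, ties.method = "first")
    kern <- if (r_ep > 1e-8) exp(-lattice_d2 / (2 * r_ep^2)) else diag(n_cells)
    wsum <- kern[, bmu, drop = FALSE] %*% feats      # cells x samples
    wtot <- rowSums(kern[, bmu, drop = FALSE])
    upd <- wtot > 0
    codes[upd, ] <- wsum[upd, , drop = FALSE] / wtot[upd]
  }
  d2 <- cross_dist2(feats, codes)
  bmu <- max.col(-d2, ties.method = "first")
  cell_of <- data.frame(feature = rownames(feats), cell = bmu,
                        row = grid$row[bmu], col = grid$col[bmu],
                        stringsAsFactors = FALSE)
  structure(list(rows = rows, cols = cols, codes = codes,
                 assignment = stats::setNames(bmu, rownames(feats)),
                 cell_of = cell_of),
            class = "wmcna_som")
}

#' Heat-map style cell comparison on a fitted SOM
#'
#' Categorizes each lattice cell by contrasting one sample (or the population
#' mean) against another for the metabolites the cell contains. Per
#' metabolite, the contrast `left - right` is compared with the metabolite's
#' population standard deviation: beyond +1 SD is `strong_up` ("red" in the
#' conventional display), between 0 and +1 SD `weak_up` ("pink"), and
#' symmetrically `weak_down`/`strong_down` ("turquoise"/"blue"); exactly zero
#' is neutral. A cell reports the most extreme category among its members
#' (a cell is "red" if any member exceeds +1 SD); up dominates down ties by
#' magnitude. Empty cells are `neutral` and flagged.
#'
#' @param som `wmcna_som` object.
#' @param x samples x features matrix the SOM was fitted to.
#' @param left,right sample id, or `"population"` for the per-metabolite mean
#'   over all samples.
#' @return data.frame: cell, row, col, n_features, category, empty.
#' @export
blsom_compare <- function(som, x, left, right = "population") {
  stopifnot(inherits(som, "wmcna_som"))
  side <- function(which) {
    if (identical(which, "population")) colMeans(x)
    else {
      if (!which %in% rownames(x)) stop("unknown sample: ", which)
      x[which, ]
    }
  }
  delta <- side(left) - side(right)
  sdv <- apply(x, 2L, stats::sd) * sqrt((nrow(x) - 1) / nrow(x))  # population SD
  unit <- ifelse(sdv > 0, delta / sdv, 0)
  grid <- expand.grid(row = seq_len(som$rows), col = seq_len(som$cols))
  cats <- vapply(seq_len(som$rows * som$cols), function(cell) {
    members <- names(som$assignment)[som$assignment == cell]
    if (length(members) == 0L) return("neutral")
    u <- unit[members]
    extreme <- u[which.max(abs(u))]
    if (extreme > 1) "strong_up"
    else if (extreme > 0) "weak_up"
    else if (extreme == 0) "neutral"
    else if (extreme >= -1) "weak_down"
    else "strong_down"
  }, character(1))
  n_feat <- tabulate(som$assignment, nbins = som$rows * som$cols)
  data.frame(cell = seq_along(cats), row = grid$row, col = grid$col,
             n_features = n_feat, category = cats, empty = n_feat == 0L,
             stringsAsFactors = FALSE)
}

#' Write a SOM lattice as TSV (cell -> member list)
#' @param som `wmcna_som` object.
#' @param path output path.
#' @export
write_som_grid <- function(som, path) {
  members <- vapply(seq_len(som$rows * som$cols), function(cell)
    paste(names(som$assignment)[som$assignment == cell], collapse = ","),
    character(1))
  grid <- expand.grid(row = seq_len(som$rows), col = seq_len(som$cols))
  df <- data.frame(cell = seq_along(members), row = grid$row, col = grid$col,
                   n_features = tabulate(som$assignment, nbins = length(members)),
                   features = members, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# squared Euclidean distances between rows of a and rows of b
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  d2
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
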