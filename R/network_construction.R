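#' Pairwise feature correlation matrix
#'
#' Computes the features x features Pearson correlation matrix of a scaled
#' abundance matrix (samples in rows). Symmetry is enforced exactly by
#' averaging with the transpose and entries are clamped to \[-1, 1\].
#'
#' @param x samples x features numeric matrix (typically from [autoscale()]).
#' @param method correlation method, `"pearson"` (default) or `"spearman"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), nrow(x) >= 3L)
  sdv <- apply(x, 2L, stats::sd)
  if (any(sdv == 0))
    stop("constant feature(s): ", paste(colnames(x)[sdv == 0], collapse = ", "))
  r <- stats::cor(x, method = method)
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Soft-threshold a correlation matrix into a weighted adjacency
#'
#' Raises correlations to the power `beta` (the soft threshold), which
#' emphasises strong links without imposing a hard cutoff. Unsigned networks
#' use `|r|^beta` so that strong negative correlations also connect nodes;
#' signed networks use `((1 + r)/2)^beta` so that anti-correlated nodes are
#' pushed apart.
#'
#' @param r correlation matrix (symmetric, unit diagonal).
#' @param power soft-threshold exponent beta > 0; default 6.
#' @param sign_mode `"unsigned"` (default) or `"signed"`.
#' @return adjacency matrix with entries in \[0, 1\] and unit diagonal.
#' @export
adjacency <- function(r, power = 6, sign_mode = c("unsigned", "signed")) {
  sign_mode <- match.arg(sign_mode)
  validate_square(r, "correlation", lo = -1, hi = 1)
  if (!is.numeric(power) || length(power) != 1L || power <= 0)
    stop("soft-threshold power must be a single positive number")
  a <- switch(sign_mode,
              unsigned = abs(r)^power,
              signed   = ((1 + r) / 2)^power)
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' The topological overlap of nodes i and j combines their direct connection
#' strength with the extent to which they share neighbors:
#' \deqn{\omega_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' with shared-neighbor weight \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}}
#' and connectivity \eqn{k_i = \sum_{u \ne i} a_{iu}}. The diagonal is 1.
#' Bounded in \[0, 1\] whenever the adjacency is.
#'
#' @param a adjacency matrix with entries in \[0, 1\].
#' @return topological overlap matrix of the same shape.
#' @export
topological_overlap <- function(a) {
  validate_square(a, "adjacency", lo = 0, hi = 1)
  a0 <- a
  diag(a0) <- 0
  l <- a0 %*% a0          # (i,j) entry sums over u != i, j since diag(a0) = 0
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  w <- (l + a0) / (kmin + 1 - a0)
  w[!is.finite(w)] <- 0   # isolated pair with a_ij = 1 cannot occur; guard anyway
  diag(w) <- 1
  dimnames(w) <- dimnames(a)
  w
}

#' Topological overlap dissimilarity
#'
#' @param w topological overlap matrix.
#' @return `1 - w`, with a zero diagonal; input to hierarchical clustering.
#' @export
dissimilarity <- function(w) {
  validate_square(w, "topological overlap", lo = 0, hi = 1)
  d <- 1 - w
  diag(d) <- 0
  d
}

#' Scale-free topology fit diagnostic
#'
#' Report-only sweep of the soft-threshold power: for each candidate beta the
#' model fit R^2 of the log-log regression of connectivity-distribution
#' frequency on binned connectivity is returned, together with mean
#' connectivity. Provided as a diagnostic; the pipeline never auto-selects a
#' power from it.
#'
#' @param r correlation matrix.
#' @param powers candidate beta values.
#' @param sign_mode passed to [adjacency()].
#' @param n_breaks histogram bins for the degree distribution.
#' @return data.frame with columns `power`, `fit_r2`, `mean_k`.
#' @export
scale_free_fit <- function(r, powers = c(1:10, seq(12, 20, 2)),
                           sign_mode = "unsigned", n_breaks = 10) {
  res <- lapply(powers, function(b) {
    a <- adjacency(r, power = b, sign_mode = sign_mode)
    k <- node_connectivity(a)
    cuts <- cut(k, breaks = n_breaks)
    dk <- tapply(k, cuts, mean)
    pk <- tabulate(as.integer(cuts), nbins = n_breaks) / length(k)
    ok <- !is.na(dk) & pk > 0 & dk > 0
    r2 <- if (sum(ok) >= 3L)
      summary(stats::lm(log10(pk[ok]) ~ log10(dk[ok])))$r.squared
    else NA_real_
    data.frame(power = b, fit_r2 = r2, mean_k = mean(k))
  })
  do.call(rbind, res)
}

#' Write a labeled matrix as TSV at full precision
#' @param m matrix with dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled matrix written by [write_matrix_tsv()]
#' @param path input path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

validate_square <- function(m, what, lo, hi, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " matrix must be square")
  if (any(!is.finite(m)))
    stop(what, " matrix contains non-finite values")
  if (max(abs(m - t(m))) > tol)
    stop(what, " matrix must be symmetric")
  if (min(m) < lo - tol || max(m) > hi + tol)
    stop(sprintf("%s entries must lie in [%g, %g]", what, lo, hi))
  invisible(m)
}
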