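# Independent triple-loop reference implementations of every network
# statistic, used as oracles against the vectorized package code. Kept
# deliberately naive: explicit sums over indices, no matrix algebra.

oracle_tom <- function(a) {
  n <- nrow(a)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { w[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      ki <- 0; kj <- 0
      for (u in seq_len(n)) {
        if (u != i) ki <- ki + a[i, u]
        if (u != j) kj <- kj + a[j, u]
      }
      w[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  dimnames(w) <- dimnames(a)
  w
}

oracle_connectivity <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in seq_len(n))
    for (j in seq_len(n)) if (j != i) k[i] <- k[i] + a[i, j]
  names(k) <- rownames(a)
  k
}

oracle_mar <- function(a) {
  n <- nrow(a)
  mar <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_len(n)) if (j != i) {
      num <- num + a[i, j]^2
      den <- den + a[i, j]
    }
    mar[i] <- if (den > 0) num / den else NA_real_
  }
  names(mar) <- rownames(a)
  mar
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    for (j in seq_len(n)) if (j != i)
      for (q in seq_len(n)) if (q != i && q != j)
        num <- num + a[i, j] * a[j, q] * a[q, i]
    k <- 0; sq <- 0
    for (j in seq_len(n)) if (j != i) { k <- k + a[i, j]; sq <- sq + a[i, j]^2 }
    den <- k^2 - sq
    cc[i] <- if (den > 0) num / den else 0
  }
  names(cc) <- rownames(a)
  cc
}

oracle_density <- function(a) {
  n <- nrow(a)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) s <- s + a[i, j]
  s / (n * (n - 1))
}

oracle_centralization <- function(a) {
  n <- nrow(a)
  if (n <= 2) return(NA_real_)
  k <- oracle_connectivity(a)
  (n / (n - 2)) * (max(k) / (n - 1) - oracle_density(a))
}

oracle_heterogeneity <- function(a) {
  k <- oracle_connectivity(a)
  if (mean(k) == 0) return(0)
  sqrt(mean(k^2) / mean(k)^2 - 1)
}

# symmetric random adjacency with unit diagonal, entries in [0, 1]
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(stats::runif(n * n), n, n)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  diag(a) <- 1
  dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  a
}
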