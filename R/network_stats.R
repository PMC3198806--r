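#' Node connectivity
#'
#' In a weighted network the connectivity of a node is the sum of its
#' connection strengths to all other nodes: \eqn{k_i = \sum_{j \ne i} a_{ij}}.
#'
#' @param a adjacency matrix.
#' @return named numeric vector of connectivities.
#' @export
node_connectivity <- function(a) {
  validate_square(a, "adjacency", lo = 0, hi = 1)
  a0 <- a
  diag(a0) <- 0
  rowSums(a0)
}

#' Scaled connectivity
#'
#' Connectivity relative to the most connected node of the evaluated network:
#' \eqn{K_i = k_i / \max_j k_j}, so the top hub scores 1.
#'
#' @param k connectivity vector from [node_connectivity()].
#' @return vector of scaled connectivities in \[0, 1\].
#' @export
scaled_connectivity <- function(k) {
  if (max(k) <= 0) stop("all connectivities are zero; scaling undefined")
  k / max(k)
}

#' Maximum adjacency ratio
#'
#' \eqn{MAR_i = \sum_{j \ne i} a_{ij}^2 / \sum_{j \ne i} a_{ij}}: a
#' weight-squared over weight sum that separates nodes with few strong
#' connections (high MAR, approaching the strongest edge weight) from nodes
#' with many weak ones (low MAR). Undefined (NA) for isolated nodes.
#'
#' @param a adjacency matrix.
#' @return named numeric vector; NA where connectivity is zero.
#' @export
max_adjacency_ratio <- function(a) {
  validate_square(a, "adjacency", lo = 0, hi = 1)
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(a0)
  mar <- rowSums(a0^2) / k
  mar[k == 0] <- NA_real_
  mar
}

#' Weighted clustering coefficient
#'
#' Measures how strongly a node's neighbors interconnect:
#' \deqn{C_i = \frac{\sum_{j \ne i} \sum_{q \ne i,j} a_{ij} a_{jq} a_{qi}}
#'                  {(\sum_{j \ne i} a_{ij})^2 - \sum_{j \ne i} a_{ij}^2}}
#' (weighted triangle weight over the number of possible neighbor pairs);
#' defined as 0 when the denominator vanishes.
#'
#' @param a adjacency matrix.
#' @return named numeric vector of clustering coefficients in \[0, 1\].
#' @export
clustering_coefficient <- function(a) {
  validate_square(a, "adjacency", lo = 0, hi = 1)
  a0 <- a
  diag(a0) <- 0
  triangles <- diag(a0 %*% a0 %*% a0)   # closed weighted 3-walks from i
  k <- rowSums(a0)
  denom <- k^2 - rowSums(a0^2)
  cc <- ifelse(denom > 0, triangles / denom, 0)
  names(cc) <- rownames(a)
  cc
}

#' Module-level network statistics
#'
#' Density, centralization and heterogeneity of the subnetwork induced by one
#' module's members:
#' density = mean off-diagonal adjacency; centralization =
#' `(n/(n-2)) * (max(k)/(n-1) - density)` for n > 2 (NA for n = 2);
#' heterogeneity = coefficient of variation of the connectivity,
#' `sqrt(mean(k^2)/mean(k)^2 - 1)`.
#'
#' @param a full-network adjacency matrix.
#' @param colors named feature -> module color vector.
#' @param module module color to summarise.
#' @return one-row data.frame: module, n_nodes, density, centralization,
#'   heterogeneity.
#' @export
module_stats <- function(a, colors, module) {
  members <- names(colors)[colors == module]
  n <- length(members)
  if (n < 2L) stop(sprintf("module '%s' has fewer than 2 members", module))
  sub <- a[members, members, drop = FALSE]
  k <- node_connectivity(sub)
  density <- sum(k) / (n * (n - 1))
  centralization <- if (n > 2L)
    (n / (n - 2)) * (max(k) / (n - 1) - density)
  else NA_real_
  heterogeneity <- if (mean(k) > 0)
    sqrt(mean(k^2) / mean(k)^2 - 1)
  else 0
  data.frame(module = module, n_nodes = n, density = density,
             centralization = centralization, heterogeneity = heterogeneity,
             stringsAsFactors = FALSE)
}

#' Per-node statistics table
#'
#' Combines connectivity, scaled connectivity, clustering coefficient and
#' maximum adjacency ratio into one table, with the module color of each
#' feature. By default statistics are computed on the whole-network adjacency
#' (`scope = "network"`); `scope = "module"` computes each node's statistics
#' on its module's induced submatrix instead (grey features are then NA).
#'
#' @param a adjacency matrix.
#' @param colors named feature -> module color vector.
#' @param scope `"network"` or `"module"`.
#' @param matrix_type label recorded in the output (`"adjacency"` by
#'   convention; pass the TOM and set `"tom"` for a TOM-based variant).
#' @return data.frame: feature, module, k, K, C, MAR.
#' @export
node_stats_table <- function(a, colors, scope = c("network", "module"),
                             matrix_type = "adjacency") {
  scope <- match.arg(scope)
  feats <- rownames(a)
  stopifnot(!is.null(feats), all(feats %in% names(colors)))
  if (scope == "network") {
    k <- node_connectivity(a)
    out <- data.frame(feature = feats, module = unname(colors[feats]),
                      k = k, K = scaled_connectivity(k),
                      C = clustering_coefficient(a),
                      MAR = max_adjacency_ratio(a),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(feature = feats, module = unname(colors[feats]),
                      k = NA_real_, K = NA_real_, C = NA_real_,
                      MAR = NA_real_, stringsAsFactors = FALSE)
    for (m in setdiff(unique(colors[feats]), "grey")) {
      members <- feats[colors[feats] == m]
      if (length(members) < 2L) next
      sub <- a[members, members, drop = FALSE]
      k <- node_connectivity(sub)
      out[out$feature %in% members, c("k", "K", "C", "MAR")] <-
        data.frame(k, scaled_connectivity(k), clustering_coefficient(sub),
                   max_adjacency_ratio(sub))
    }
  }
  attr(out, "matrix_type") <- matrix_type
  rownames(out) <- NULL
  out
}
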