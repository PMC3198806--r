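#' Hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering of features by topological-overlap dissimilarity.
#' Average linkage (UPGMA) is the field default; the underlying
#' implementation breaks ties deterministically.
#'
#' @param d symmetric dissimilarity matrix (zero diagonal).
#' @param linkage linkage criterion passed to [stats::hclust()].
#' @return an object of class `hclust`.
#' @export
hierarchical_cluster <- function(d, linkage = "average") {
  validate_square(d, "dissimilarity", lo = 0, hi = 1)
  if (nrow(d) < 2L) stop("clustering needs at least 2 features")
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Cut a dendrogram into modules at a static height
#'
#' Cuts the tree at `cut_height`; clusters smaller than `min_module_size` are
#' relabeled as unassigned ("grey"). The default height is a fraction of the
#' maximum merge height so the cut adapts to the tree scale.
#'
#' @param dend an `hclust` object from [hierarchical_cluster()].
#' @param cut_height absolute cut height; default `0.95 * max(dend$height)`.
#' @param min_module_size smallest cluster kept as a module (default 3).
#' @param method `"static"` (default) cuts at a fixed height. `"hybrid"`
#'   additionally rescues grey features: a pruned feature joins the module
#'   whose members it overlaps most, provided its mean topological overlap
#'   with that module exceeds `rescue_threshold` (requires `tom`).
#' @param tom topological overlap matrix, required for `method = "hybrid"`.
#' @param rescue_threshold minimum mean overlap for hybrid rescue.
#' @return named character vector feature -> provisional module label
#'   (`"1"`, `"2"`, ... by dendrogram order) with `"grey"` for unassigned;
#'   pass to [assign_colors()] for conventional color names.
#' @export
cut_modules <- function(dend, cut_height = NULL, min_module_size = 3,
                        method = c("static", "hybrid"), tom = NULL,
                        rescue_threshold = 0.15) {
  method <- match.arg(method)
  stopifnot(inherits(dend, "hclust"), min_module_size >= 2)
  if (method == "hybrid" && is.null(tom))
    stop("hybrid cut requires the topological overlap matrix")
  cut_height <- cut_height %||% (0.95 * max(dend$height))
  if (cut_height <= 0) stop("cut height must be positive")
  cl <- stats::cutree(dend, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- ifelse(as.character(cl) %in% keep, as.character(cl), "grey")
  names(labels) <- names(cl)
  if (method == "hybrid" && any(labels == "grey") && length(keep) > 0L) {
    for (f in names(labels)[labels == "grey"]) {
      mean_overlap <- vapply(keep, function(m) {
        members <- setdiff(names(labels)[labels == m], f)
        mean(tom[f, members])
      }, numeric(1))
      best <- which.max(mean_overlap)
      if (mean_overlap[best] >= rescue_threshold)
        labels[f] <- keep[best]
    }
  }
  if (all(labels == "grey"))
    warning("no module met the minimum size; all features are grey")
  labels
}

#' Rename modules along the conventional color sequence
#'
#' Modules are ordered by decreasing size (ties broken by first-feature
#' position) and renamed turquoise, blue, brown, yellow, ... in the standard
#' module palette. The reserved label "grey" is preserved for unassigned
#' features.
#'
#' @param labels named character vector from [cut_modules()].
#' @param palette color sequence to use; override to match a house style.
#' @return named character vector feature -> color.
#' @export
assign_colors <- function(labels, palette = module_palette()) {
  mods <- setdiff(unique(labels), "grey")
  if (length(mods) == 0L) return(labels)
  first_pos <- vapply(mods, function(m) min(which(labels == m)), numeric(1))
  sizes <- vapply(mods, function(m) sum(labels == m), numeric(1))
  mods <- mods[order(-sizes, first_pos)]
  if (length(mods) > length(palette))
    palette <- c(palette, paste0("module", seq_len(length(mods) - length(palette))))
  map <- stats::setNames(palette[seq_along(mods)], mods)
  out <- ifelse(labels == "grey", "grey", map[labels])
  names(out) <- names(labels)
  out
}

#' Conventional module color sequence
#' @return character vector of color names ordered as conventionally assigned
#'   to modules of decreasing size ("grey" is reserved for unassigned).
#' @export
module_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta")
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths encode merge heights, so tree viewers reproduce the
#' clustering geometry.
#'
#' @param dend `hclust` object.
#' @param path output path.
#' @export
write_dendrogram_newick <- function(dend, path) {
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}

#' Export a dendrogram merge table as TSV
#' @param dend `hclust` object.
#' @param path output path.
#' @export
write_dendrogram_merges <- function(dend, path) {
  df <- data.frame(step = seq_along(dend$height),
                   left = dend$merge[, 1L], right = dend$merge[, 2L],
                   height = dend$height)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a module assignment as a two-column TSV
#' @param colors named character vector feature -> color.
#' @param path output path.
#' @export
write_module_assignment <- function(colors, path) {
  df <- data.frame(feature = names(colors), module = unname(colors))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label permutation), about 0 for independent
#' ones. Used to score recovery of planted modules.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return adjusted Rand index in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
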