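#' Module eigenmetabolite
#'
#' The representative abundance profile of a module: the first left singular
#' vector of the samples x members submatrix of the scaled data (equivalently
#' the first principal-component score vector), of unit norm. The sign is
#' oriented so the eigenmetabolite correlates non-negatively with the
#' module's mean profile; if that correlation is exactly zero, the member
#' with the largest absolute loading is made positive. `variance_explained`
#' is the fraction of the module's total variance captured by the first
#' component.
#'
#' @param x scaled samples x features matrix (see [autoscale()]).
#' @param colors named feature -> module color vector.
#' @param module module color.
#' @return list of class `wmcna_eigen`: `module`, `scores` (named,
#'   unit-norm), `variance_explained`, `loadings` (per member).
#' @export
eigenmetabolite <- function(x, colors, module) {
  members <- intersect(colnames(x), names(colors)[colors == module])
  if (length(members) < 2L)
    stop(sprintf("module '%s' needs at least 2 members", module))
  sub <- x[, members, drop = FALSE]
  if (all(sub == 0)) stop("module submatrix is identically zero")
  sv <- svd(sub)
  scores <- sv$u[, 1L]
  varexp <- sv$d[1L]^2 / sum(sv$d^2)
  mean_profile <- rowMeans(sub)
  orient <- sum(scores * mean_profile)
  if (orient < 0) {
    scores <- -scores
  } else if (orient == 0) {
    load1 <- sv$v[, 1L]
    if (load1[which.max(abs(load1))] < 0) scores <- -scores
  }
  loadings <- drop(crossprod(sub, scores)) / sv$d[1L]
  names(scores) <- rownames(x)
  names(loadings) <- members
  structure(list(module = module, scores = scores,
                 variance_explained = varexp, loadings = loadings),
            class = "wmcna_eigen")
}

#' Eigenmetabolites for all modules
#'
#' @param x scaled samples x features matrix.
#' @param colors named feature -> module color vector.
#' @param include_grey compute a profile for the unassigned pool too?
#' @return samples x modules matrix of eigenmetabolite scores.
#' @export
eigenmetabolite_matrix <- function(x, colors, include_grey = FALSE) {
  mods <- setdiff(unique(colors), if (include_grey) character(0) else "grey")
  mods <- mods[vapply(mods, function(m) sum(colors == m) >= 2L, logical(1))]
  if (length(mods) == 0L) stop("no module with at least 2 members")
  scores <- vapply(mods, function(m) eigenmetabolite(x, colors, m)$scores,
                   numeric(nrow(x)))
  rownames(scores) <- rownames(x)
  scores
}

#' One-way ANOVA of an eigenmetabolite on a categorical trait
#'
#' Fixed-effects one-way ANOVA of eigenmetabolite scores on a sample factor
#' (e.g. genotype), with the significance threshold Bonferroni-adjusted for
#' the number of modules tested: `alpha_adj = alpha / n_modules` (0.05/3 =
#' 0.0167 for three modules). Per-level letters come from pairwise Welch
#' t-tests at `alpha_adj` summarised by [compact_letter_display()]: levels
#' that share no letter differ at the adjusted threshold.
#'
#' @param eig `wmcna_eigen` object (or a named score vector).
#' @param traits trait data.frame (see [read_trait_table()]).
#' @param factor_name column of `traits` to test.
#' @param n_modules number of modules tested (Bonferroni divisor).
#' @param alpha family-wise error rate before adjustment (default 0.05).
#' @return list of class `wmcna_anova`: `module`, `factor_name`, `F`, `df`,
#'   `p`, `alpha_adj`, `significant`, `level_means` (mean, se, n per level),
#'   `letters`.
#' @export
module_trait_anova <- function(eig, traits, factor_name, n_modules,
                               alpha = 0.05) {
  scores <- if (inherits(eig, "wmcna_eigen")) eig$scores else eig
  module <- if (inherits(eig, "wmcna_eigen")) eig$module else NA_character_
  if (!factor_name %in% colnames(traits))
    stop(sprintf("factor '%s' not present in trait table", factor_name))
  idx <- match(traits$sample, names(scores))
  if (any(is.na(idx)))
    stop("trait table contains samples absent from the eigenmetabolite")
  y <- scores[idx]
  g <- droplevels(traits[[factor_name]])
  if (nlevels(g) < 2L) stop("factor needs at least 2 levels")
  n_per <- table(g)
  if (any(n_per < 2L))
    stop("every factor level needs at least 2 samples; too few in: ",
         paste(names(n_per)[n_per < 2L], collapse = ", "))
  fit <- stats::anova(stats::lm(y ~ g))
  Fstat <- fit$`F value`[1L]
  p <- fit$`Pr(>F)`[1L]
  alpha_adj <- alpha / n_modules
  lv <- levels(g)
  level_means <- data.frame(
    level = lv,
    mean = vapply(lv, function(l) mean(y[g == l]), numeric(1)),
    se = vapply(lv, function(l) stats::sd(y[g == l]) / sqrt(sum(g == l)),
                numeric(1)),
    n = as.integer(n_per[lv]), stringsAsFactors = FALSE)
  pw <- pairwise_welch(y, g)
  letters <- compact_letter_display(pw, alpha_adj)
  structure(list(module = module, factor_name = factor_name,
                 F = Fstat, df = c(fit$Df[1L], fit$Df[2L]), p = p,
                 alpha_adj = alpha_adj, significant = p < alpha_adj,
                 level_means = level_means, letters = letters),
            class = "wmcna_anova")
}

#' Pairwise Welch t-test p-values between factor levels
#'
#' @param y numeric response.
#' @param g factor of group labels.
#' @return data.frame with columns `a`, `b`, `p` for every unordered level
#'   pair. Identical value multisets give p = 1 (zero pooled variance).
#' @export
pairwise_welch <- function(y, g) {
  g <- droplevels(as.factor(g))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2L)
  p <- apply(pairs, 2L, function(pr) {
    ya <- y[g == pr[1L]]; yb <- y[g == pr[2L]]
    if (stats::sd(ya) == 0 && stats::sd(yb) == 0)
      return(if (mean(ya) == mean(yb)) 1 else 0)
    stats::t.test(ya, yb)$p.value
  })
  data.frame(a = pairs[1L, ], b = pairs[2L, ], p = p,
             stringsAsFactors = FALSE)
}

#' Compact letter display from pairwise p-values
#'
#' Insert-and-absorb algorithm: starting from one letter shared by all
#' levels, every significant pair splits the letter sets containing both
#' members, and sets contained in another set are absorbed. The result is a
#' minimal letter assignment in which levels sharing a letter are pairwise
#' non-significant and significant pairs never share any letter.
#'
#' @param pairwise data.frame with columns `a`, `b`, `p` (one row per
#'   unordered level pair).
#' @param alpha significance threshold.
#' @return named character vector level -> letter string (e.g. `"ab"`).
#' @export
compact_letter_display <- function(pairwise, alpha) {
  lv <- unique(c(pairwise$a, pairwise$b))
  sets <- list(lv)
  sig <- pairwise[pairwise$p < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    x <- sig$a[i]; y <- sig$b[i]
    hit <- vapply(sets, function(s) x %in% s && y %in% s, logical(1))
    if (!any(hit)) next
    new_sets <- sets[!hit]
    for (s in sets[hit])
      new_sets <- c(new_sets, list(setdiff(s, x)), list(setdiff(s, y)))
    # absorb sets fully contained in another
    keep <- rep(TRUE, length(new_sets))
    for (j in seq_along(new_sets)) {
      for (k in seq_along(new_sets)) {
        if (j == k || !keep[j]) next
        if (all(new_sets[[j]] %in% new_sets[[k]]) &&
            (length(new_sets[[j]]) < length(new_sets[[k]]) || j > k)) {
          keep[j] <- FALSE
          break
        }
      }
    }
    sets <- new_sets[keep]
  }
  sets <- sets[vapply(sets, length, integer(1)) > 0L]
  ord <- order(vapply(sets, function(s) min(match(s, lv)), numeric(1)))
  sets <- sets[ord]
  out <- stats::setNames(rep("", length(lv)), lv)
  for (j in seq_along(sets))
    out[sets[[j]]] <- paste0(out[sets[[j]]], letters[j])
  out
}

#' Write a samples x modules eigenmetabolite matrix as TSV
#' @param scores matrix from [eigenmetabolite_matrix()].
#' @param path output path.
#' @export
write_eigenmetabolites <- function(scores, path) {
  write_matrix_tsv(scores, path)
}

#' Write ANOVA results as a TSV report
#' @param results list of `wmcna_anova` objects.
#' @param path output path.
#' @export
write_anova_report <- function(results, path) {
  rows <- lapply(results, function(r) {
    lm <- r$level_means
    data.frame(module = r$module, factor = r$factor_name,
               F = r$F, df1 = r$df[1L], df2 = r$df[2L], p = r$p,
               alpha_adj = r$alpha_adj, significant = r$significant,
               level = lm$level, mean = lm$mean, se = lm$se, n = lm$n,
               letters = unname(r$letters[lm$level]),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
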