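#' Specification of a synthetic metabolomic study design
#'
#' Describes a balanced multi-genotype design with planted co-abundance
#' blocks: per block a shared latent factor gives every member pairwise
#' within-block correlation `rho_within`, and per-group mean shifts (in SD
#' units) emulate genotype/ripeness effects on whole blocks. Defaults mirror
#' a 6-genotype x 10-fruit tomato panel with 46 metabolite features in blocks
#' of 13, 12 and 6 plus 15 unstructured background features, with the larger
#' two blocks elevated in fully ripe genotypes, the second additionally
#' shifted by genetic background, and the third high in the modern background
#' except its hybrid.
#'
#' @param n_per_group samples per group (default 10).
#' @param groups group labels (default the 6-genotype panel).
#' @param block_sizes sizes of the planted co-abundance blocks.
#' @param n_background number of independent background features.
#' @param rho_within target pairwise correlation inside each block, in
#'   \[0, 1).
#' @param effect_size scale (in SD units) of the default effect map.
#' @param effect_map list (one element per block) of named numeric vectors
#'   group -> mean shift in SD units; `NULL` builds the default pattern
#'   scaled by `effect_size`. Use `effect_size = 0` for a null design.
#' @param baseline location added before output so concentrations are
#'   positive (arbitrary units).
#' @return list of class `wmcna_synth_spec`.
#' @export
synthetic_spec <- function(n_per_group = 10,
                           groups = c("AC", "AC_rin", "AC_tg_rin",
                                      "NC", "NC_rin", "NC_F1"),
                           block_sizes = c(13, 12, 6),
                           n_background = 15,
                           rho_within = 0.8,
                           effect_size = 1.5,
                           effect_map = NULL,
                           baseline = 8) {
  stopifnot(n_per_group >= 2, length(groups) >= 1, all(block_sizes >= 2),
            rho_within >= 0, rho_within < 1, n_background >= 0)
  if (is.null(effect_map))
    effect_map <- default_effect_map(groups, length(block_sizes), effect_size)
  stopifnot(length(effect_map) == length(block_sizes))
  for (em in effect_map)
    if (!all(names(em) %in% groups))
      stop("effect map names a group absent from the design")
  structure(list(n_per_group = n_per_group, groups = groups,
                 block_sizes = block_sizes, n_background = n_background,
                 rho_within = rho_within, effect_map = effect_map,
                 baseline = baseline),
            class = "wmcna_synth_spec")
}

# Default genotype effect pattern: ripeness drives blocks 1-2, genetic
# background additionally drives block 2, and block 3 is high in the modern
# background parents but not their hybrid. Groups outside the default panel
# get no effect.
default_effect_map <- function(groups, n_blocks, effect_size) {
  ripe <- c(AC = 1, AC_rin = 0, AC_tg_rin = 0.5,
            NC = 1, NC_rin = 0, NC_F1 = 0.5)
  background <- c(AC = 0, AC_rin = 0, AC_tg_rin = 0,
                  NC = 1, NC_rin = 1, NC_F1 = 1)
  parents_not_hybrid <- c(AC = 0, AC_rin = 0, AC_tg_rin = 0,
                          NC = 1, NC_rin = 1, NC_F1 = 0)
  zero <- stats::setNames(rep(0, length(groups)), groups)
  pick <- function(v) {
    out <- zero
    shared <- intersect(groups, names(v))
    out[shared] <- v[shared]
    out * effect_size
  }
  patterns <- list(pick(ripe),
                   pick(ripe) + pick(background),
                   pick(parents_not_hybrid))
  rep_len(patterns, n_blocks)
}

#' Generate a synthetic abundance matrix with planted modules
#'
#' Per block, each member is `sqrt(rho) * g + sqrt(1 - rho) * e` with a
#' shared per-sample latent factor `g` and independent noise `e` (both
#' standard normal), which gives exact population correlation `rho` between
#' any two members and guarantees a positive-definite covariance without a
#' Cholesky factorization. Group mean shifts from the effect map are added on
#' the same SD scale. Background features are independent standard normal.
#' A constant baseline shifts all values onto a positive concentration
#' scale; autoscaling removes it again downstream.
#'
#' @param spec `wmcna_synth_spec` from [synthetic_spec()].
#' @param seed integer seed; output is deterministic given spec and seed.
#' @return list: `abundance` (samples x features matrix), `traits`
#'   (data.frame with genotype, background, ripeness), `truth` (named feature
#'   -> block label vector, background features labeled `"grey"`).
#' @export
generate_synthetic <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "wmcna_synth_spec"))
  with_seed(seed, {
    n_groups <- length(spec$groups)
    n <- spec$n_per_group * n_groups
    group <- factor(rep(spec$groups, each = spec$n_per_group),
                    levels = spec$groups)
    n_feat <- sum(spec$block_sizes) + spec$n_background
    z <- matrix(NA_real_, n, n_feat)
    truth <- character(n_feat)
    feat_names <- character(n_feat)
    col <- 0L
    for (b in seq_along(spec$block_sizes)) {
      size <- spec$block_sizes[b]
      g <- stats::rnorm(n)
      shift <- spec$effect_map[[b]][as.character(group)]
      shift[is.na(shift)] <- 0
      for (j in seq_len(size)) {
        col <- col + 1L
        z[, col] <- sqrt(spec$rho_within) * g +
          sqrt(1 - spec$rho_within) * stats::rnorm(n) + shift
        truth[col] <- paste0("block", b)
        feat_names[col] <- sprintf("met_b%d_%02d", b, j)
      }
    }
    for (j in seq_len(spec$n_background)) {
      col <- col + 1L
      z[, col] <- stats::rnorm(n)
      truth[col] <- "grey"
      feat_names[col] <- sprintf("met_bg_%02d", j)
    }
    abundance <- pmax(z + spec$baseline, 0)
    rownames(abundance) <- sprintf("%s_f%02d", as.character(group),
                                   rep(seq_len(spec$n_per_group), n_groups))
    colnames(abundance) <- feat_names
    traits <- data.frame(
      sample = rownames(abundance),
      genotype = group,
      background = factor(ifelse(grepl("^NC", as.character(group)), "NC", "AC")),
      ripeness = factor(ripeness_of(as.character(group)),
                        levels = c("full", "partial", "none")),
      stringsAsFactors = FALSE)
    list(abundance = abundance, traits = traits,
         truth = stats::setNames(truth, feat_names))
  })
}

ripeness_of <- function(genotype) {
  map <- c(AC = "full", AC_rin = "none", AC_tg_rin = "partial",
           NC = "full", NC_rin = "none", NC_F1 = "partial")
  out <- map[genotype]
  out[is.na(out)] <- "none"
  unname(out)
}

#' Write the three synthetic tables (abundance, traits, truth) to a directory
#' @param sim result of [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ab <- file.path(dir, "abundance.tsv")
  tr <- file.path(dir, "traits.tsv")
  th <- file.path(dir, "truth.tsv")
  write_abundance_table(sim$abundance, ab)
  write_trait_table(sim$traits, tr)
  utils::write.table(
    data.frame(feature = names(sim$truth), block = unname(sim$truth)),
    th, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(abundance = ab, traits = tr, truth = th))
}
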