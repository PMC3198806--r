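#' Read a samples x metabolites abundance table
#'
#' Reads a delimited text file whose first row holds feature (metabolite)
#' names and whose first column holds sample identifiers, returning a numeric
#' samples x features matrix. The delimiter is auto-detected from the file
#' extension (`.csv` is comma, anything else tab) unless given explicitly.
#' Parsing is locale-independent (dot decimal separator).
#'
#' @param path path to the delimited text file.
#' @param sep field delimiter; `NULL` (default) auto-detects from extension.
#' @return a numeric matrix with sample ids as rownames and feature ids as
#'   colnames; all values finite and non-negative checks are left to callers
#'   that require them.
#' @export
read_abundance_table <- function(path, sep = NULL) {
  sep <- sep %||% detect_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty abundance table: need at least one sample row and one feature column")
  sample_ids <- raw[[1L]]
  feature_ids <- colnames(raw)[-1L]
  check_unique_ids(sample_ids, "sample")
  check_unique_ids(feature_ids, "feature")
  body <- as.matrix(raw[, -1L, drop = FALSE])
  values <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-numeric or missing cell '%s' at sample '%s', feature '%s'",
      body[bad[1L, 1L], bad[1L, 2L]], sample_ids[bad[1L, 1L]],
      feature_ids[bad[1L, 2L]]))
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  values
}

#' Write an abundance matrix as a delimited table
#'
#' Inverse of [read_abundance_table()]: writes full-precision values so that a
#' read/write round trip is exact up to float formatting.
#'
#' @param m samples x features numeric matrix with dimnames.
#' @param path output path.
#' @param sep field delimiter; auto-detected from extension by default.
#' @param id_column header for the sample-id column.
#' @export
write_abundance_table <- function(m, path, sep = NULL, id_column = "sample") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  sep <- sep %||% detect_sep(path)
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample trait table
#'
#' Reads a delimited file with a sample-id column followed by one or more
#' categorical factor columns (e.g. genotype, genetic background, ripeness).
#'
#' @param path path to the delimited text file.
#' @param sep field delimiter; auto-detected from extension by default.
#' @param abundance optional abundance matrix to validate against: every
#'   sample id of the matrix must be present in the trait table.
#' @return a data.frame with a `sample` column of ids and one factor column
#'   per trait; factor level order follows first appearance.
#' @export
read_trait_table <- function(path, sep = NULL, abundance = NULL) {
  sep <- sep %||% detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("trait table needs a sample-id column plus at least one factor column")
  colnames(df)[1L] <- "sample"
  check_unique_ids(df$sample, "sample")
  for (fac in colnames(df)[-1L]) {
    empty <- which(is.na(df[[fac]]) | !nzchar(trimws(df[[fac]])))
    if (length(empty) > 0L)
      stop(sprintf("empty level for factor '%s' at sample '%s'",
                   fac, df$sample[empty[1L]]))
    df[[fac]] <- factor(df[[fac]], levels = unique(df[[fac]]))
  }
  if (!is.null(abundance)) {
    missing <- setdiff(rownames(abundance), df$sample)
    if (length(missing) > 0L)
      stop("trait table is missing samples: ", paste(missing, collapse = ", "))
  }
  df
}

#' Write a trait table
#' @param traits data.frame as returned by [read_trait_table()].
#' @param path output path.
#' @param sep field delimiter; auto-detected from extension by default.
#' @export
write_trait_table <- function(traits, path, sep = NULL) {
  sep <- sep %||% detect_sep(path)
  out <- traits
  out[] <- lapply(out, as.character)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Autoscale an abundance matrix
#'
#' Standardizes each feature (column) to mean 0 and unit sample standard
#' deviation (n - 1 denominator), the conventional pre-treatment that stops
#' high-concentration metabolites from dominating correlation, PCA and SOM
#' analyses. Constant features cannot be scaled (sd = 0); they are set to
#' all-zero and recorded in the `"constant_features"` attribute so that
#' downstream network construction can exclude them.
#'
#' @param m samples x features numeric matrix.
#' @return matrix of the same shape with class `"wmcna_scaled"` and attribute
#'   `constant_features` (character vector, possibly empty).
#' @export
autoscale <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (nrow(m) < 2L)
    stop("autoscaling needs at least 2 samples (sd undefined for n = 1)")
  if (any(!is.finite(m))) stop("abundance matrix contains non-finite values")
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  constant <- colnames(m)[sdv == 0]
  sdv[sdv == 0] <- 1  # constant columns become all-zero after centering
  out <- sweep(sweep(m, 2L, mu, "-"), 2L, sdv, "/")
  structure(out, constant_features = constant, class = c("wmcna_scaled", class(out)))
}

#' Bin a set of 1D NMR spectra into a fingerprint feature table
#'
#' Tiles the interval `[lo, hi)` with half-open bins `[b, b + width)` of equal
#' width, drops every bin whose interval intersects an exclusion window (such
#' as the residual water region), and aggregates each sample's intensities
#' within each surviving bin. With the conventional settings lo = 0.5 ppm,
#' hi = 10 ppm, width = 0.02 ppm and the water region 4.5-5 ppm excluded this
#' yields a 450-feature fingerprint.
#'
#' @param ppm numeric vector, the chemical-shift axis (strictly monotone; a
#'   descending axis, the usual NMR display order, is accepted).
#' @param intensities samples x points matrix (or a single numeric vector)
#'   aligned to `ppm`.
#' @param lo,hi bin range in ppm (`lo < hi`).
#' @param width bin width in ppm.
#' @param exclusions list of length-2 numeric vectors, half-open ppm windows
#'   `[e1, e2)` to exclude.
#' @param agg aggregation within a bin: `"sum"` or `"mean"`.
#' @return samples x bins matrix; columns named by bin-center ppm.
#' @export
bin_spectrum <- function(ppm, intensities, lo = 0.5, hi = 10, width = 0.02,
                         exclusions = list(c(4.5, 5.0)), agg = c("sum", "mean")) {
  agg <- match.arg(agg)
  if (!is.matrix(intensities)) intensities <- matrix(intensities, nrow = 1L)
  stopifnot(length(ppm) == ncol(intensities), lo < hi, width > 0)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0))) stop("ppm axis must be strictly monotone")
  if (all(d < 0)) {  # accept the usual descending NMR display order
    ppm <- rev(ppm)
    intensities <- intensities[, ncol(intensities):1L, drop = FALSE]
  }
  for (ex in exclusions)
    if (length(ex) != 2L || ex[1L] >= ex[2L] || ex[1L] < lo || ex[2L] > hi)
      stop("each exclusion must be an increasing interval within [lo, hi]")
  n_bins <- round((hi - lo) / width)
  starts <- lo + width * (seq_len(n_bins) - 1L)
  eps <- width * 1e-9  # guard float jitter at aligned bin edges
  keep <- rep(TRUE, n_bins)
  for (ex in exclusions)
    keep <- keep & !(starts < ex[2L] - eps & starts + width > ex[1L] + eps)
  if (!any(keep)) stop("no bins survive the exclusion windows")
  idx <- as.integer(floor((ppm - lo) / width)) + 1L
  in_range <- idx >= 1L & idx <= n_bins
  counts <- tabulate(idx[in_range], nbins = n_bins)
  out <- matrix(0, nrow(intensities), n_bins)
  if (any(in_range)) {
    # rowsum aggregates axis points by bin index in one pass
    sums <- rowsum(t(intensities[, in_range, drop = FALSE]), idx[in_range])
    out[, as.integer(rownames(sums))] <- t(sums)
  }
  if (agg == "mean")
    out <- sweep(out, 2L, pmax(counts, 1L), "/")
  out <- out[, keep, drop = FALSE]
  colnames(out) <- sprintf("%.3f", starts[keep] + width / 2)
  rownames(out) <- rownames(intensities) %||% paste0("sample_", seq_len(nrow(out)))
  out
}

# -- internal helpers ---------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

detect_sep <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

check_unique_ids <- function(ids, what) {
  if (any(is.na(ids)) || any(!nzchar(ids)))
    stop(sprintf("empty %s id", what))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop(sprintf("duplicate %s id: %s", what, dup[1L]))
  invisible(ids)
}
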