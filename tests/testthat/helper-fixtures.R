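# In-code fixtures shared across test files.

toy_abundance <- function() {
  m <- matrix(c(1, 2, 3, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("f1", "f2")))
  m
}

# two tight blocks of 5 features each: within-block dissimilarity 0,
# between-block 1 (as a plain matrix, not data-derived)
two_block_dissimilarity <- function() {
  d <- matrix(1, 10, 10)
  d[1:5, 1:5] <- 0
  d[6:10, 6:10] <- 0
  diag(d) <- 0
  dimnames(d) <- list(paste0("f", 1:10), paste0("f", 1:10))
  d
}

# unit star adjacency: node 1 is the hub
unit_star <- function(n = 4) {
  a <- matrix(0, n, n)
  a[1, -1] <- 1
  a[-1, 1] <- 1
  diag(a) <- 1
  dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  a
}

unit_complete <- function(n = 4) {
  a <- matrix(1, n, n)
  dimnames(a) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  a
}

write_tsv_fixture <- function(lines, ext = "tsv") {
  path <- withr::local_tempfile(fileext = paste0(".", ext),
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
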