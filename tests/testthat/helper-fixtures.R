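# Shared fixture builders for the test suite.  Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# A small gene table on two chromosomes with a centromere at 5e5.
tiny_genes <- function() {
  gene_table(
    data.frame(
      gene_id = paste0("g", 1:6),
      chromosome = c("1", "1", "1", "2", "2", "2"),
      start = c(100e3, 300e3, 700e3, 100e3, 650e3, 900e3),
      end   = c(120e3, 340e3, 760e3, 140e3, 680e3, 990e3),
      strand = c("+", "-", "+", "+", "-", "+"),
      biotype = "protein_coding",
      stringsAsFactors = FALSE),
    centromeres = c("1" = 5e5, "2" = 5e5))
}

# An identity-correlation eigenbasis over the given gene ids.
identity_basis <- function(ids, fraction = 1.0) {
  om <- diag(length(ids))
  dimnames(om) <- list(ids, ids)
  truncate_eigen(om, fraction)
}

# A random positive-definite correlation matrix with gene ids.
random_corr <- function(n, seed = 1, prefix = "g") {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  M <- cov2cor(crossprod(A) + diag(n))
  ids <- paste0(prefix, seq_len(n))
  dimnames(M) <- list(ids, ids)
  M
}

# Write a summary-statistics TSV and return the path.
write_sumstats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Write GMT lines and return the path.
write_gmt_file <- function(lines, path = tempfile(fileext = ".gmt")) {
  writeLines(lines, path)
  path
}

# Exact two-sided Fisher p by hypergeometric enumeration (the independent
# oracle: sum of all tables, at the observed margins, whose probability does
# not exceed the observed table's).
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  dens <- dhyper(x, m, n, k)
  sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-7)])
}
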