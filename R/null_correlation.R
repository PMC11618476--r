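# The gene-gene correlation matrix Omega estimated from many simulated null
# GWASs, and its truncated eigenbasis.  LD does not cross chromosome arms,
# so Omega is block-diagonal per arm: correlations are computed within arms
# and set to exactly zero across them, and the eigendecomposition is done
# per block (mathematically identical to decomposing the assembled matrix).

#' Build the gene-gene correlation matrix from null GWAS gene z-scores
#'
#' Pearson correlations between gene z-scores across the simulated null
#' GWASs are computed separately per chromosome arm; entries for gene pairs
#' on different arms are exactly zero because LD cannot span a centromere.
#' Since the null phenotypes are random, any correlation that remains
#' reflects only the LD structure and chromosomal organisation of genes.
#'
#' @param null_z genes x traits matrix of gene z-scores from null GWASs
#'   (e.g. `score_genes(...)$z` on a [simulate_null_gwas()] set), gene ids
#'   as rownames.
#' @param genes a [gene_table()]; only genes present in `null_z` are used.
#' @return an `omega_matrix`: list with `genes` (ordered ids), `arm` (factor
#'   of `"chrom_arm"` labels per gene), `blocks` (named list of within-arm
#'   correlation matrices), `n_null_gwas`.
#' @export
build_omega <- function(null_z, genes) {
  check_that(is.matrix(null_z) && ncol(null_z) >= 2,
             "need a genes x traits matrix with >= 2 null GWASs")
  if (ncol(null_z) == 2L)
    warning("only 2 null GWASs: within-arm correlations are degenerate (+/-1)")
  ids <- intersect(genes$gene_id, rownames(null_z))
  check_that(length(ids) > 0, "no overlap between genes and null_z rownames")
  arm_label <- paste0(genes$chromosome, "_", genes$arm)
  names(arm_label) <- genes$gene_id
  arm <- arm_label[ids]
  blocks <- lapply(split(ids, arm), function(block_ids) {
    Z <- t(null_z[block_ids, , drop = FALSE])
    sds <- apply(Z, 2, stats::sd)
    R <- suppressWarnings(stats::cor(Z))
    if (any(sds == 0)) {
      message(sum(sds == 0), " gene(s) with constant null z: ",
              "off-diagonal correlations set to 0")
      R[sds == 0, ] <- 0; R[, sds == 0] <- 0
    }
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    R
  })
  structure(list(genes = ids, arm = arm, blocks = blocks,
                 n_null_gwas = ncol(null_z)),
            class = "omega_matrix")
}

#' @export
print.omega_matrix <- function(x, ...) {
  cat("Gene-gene null correlation matrix:", length(x$genes), "genes in",
      length(x$blocks), "chromosome-arm block(s), estimated from",
      x$n_null_gwas, "null GWASs\n")
  invisible(x)
}

#' Assemble the full (block-diagonal) correlation matrix
#'
#' @param omega a [build_omega()] result.
#' @return dense genes x genes matrix with zeros across arms.
#' @export
as_matrix <- function(omega) UseMethod("as_matrix")

#' @rdname as_matrix
#' @export
as_matrix.omega_matrix <- function(omega) {
  n <- length(omega$genes)
  M <- matrix(0, n, n, dimnames = list(omega$genes, omega$genes))
  for (b in omega$blocks) M[rownames(b), colnames(b)] <- b
  M
}

#' Truncated eigenbasis of the gene-gene correlation matrix
#'
#' Eigendecomposition is performed per arm block and assembled — identical
#' to decomposing the full block-diagonal matrix, at a fraction of the cost.
#' Because the matrix is an estimated correlation matrix it need not be
#' positive-definite; negative eigenvalues are clipped to zero before the
#' cumulative-variance scan.  The smallest set of leading eigenvectors whose
#' eigenvalue sum reaches `variance_fraction` of the total is retained,
#' discarding the small-eigenvalue directions that mostly describe noise.
#'
#' @param omega an [build_omega()] result (or a plain symmetric matrix with
#'   dimnames, treated as one block).
#' @param variance_fraction fraction of total variance to retain, in (0, 1]
#'   (default 0.90).
#' @return an `eigen_basis`: list with `values` (retained eigenvalues,
#'   descending), `vectors` (genes x retained orthonormal matrix), `genes`,
#'   `variance_fraction_retained` (achieved fraction), `n_total`
#'   (full dimension).
#' @export
truncate_eigen <- function(omega, variance_fraction = 0.90) {
  check_that(variance_fraction > 0 && variance_fraction <= 1,
             "variance_fraction must be in (0, 1]")
  if (is.matrix(omega)) {
    check_that(!is.null(rownames(omega)), "matrix omega needs gene rownames")
    omega <- structure(list(genes = rownames(omega),
                            blocks = list(all = omega)),
                       class = "omega_matrix")
  }
  eigs <- lapply(omega$blocks, function(B) eigen(B, symmetric = TRUE))
  values <- unlist(lapply(eigs, `[[`, "values"), use.names = FALSE)
  values <- pmax(values, 0)
  # embed each block's eigenvectors into the full gene space
  n <- length(omega$genes)
  k_all <- length(values)
  V <- matrix(0, n, k_all, dimnames = list(omega$genes, NULL))
  at <- 0L
  for (b in seq_along(eigs)) {
    ids <- rownames(omega$blocks[[b]])
    kb <- ncol(eigs[[b]]$vectors)
    V[ids, at + seq_len(kb)] <- eigs[[b]]$vectors
    at <- at + kb
  }
  ord <- order(values, decreasing = TRUE)
  values <- values[ord]; V <- V[, ord, drop = FALSE]
  total <- sum(values)
  k <- which(cumsum(values) >= variance_fraction * total - 1e-12)[1]
  structure(list(values = values[seq_len(k)],
                 vectors = V[, seq_len(k), drop = FALSE],
                 genes = omega$genes,
                 variance_fraction_retained = sum(values[seq_len(k)]) / total,
                 n_total = k_all),
            class = "eigen_basis")
}

#' @export
print.eigen_basis <- function(x, ...) {
  cat("Truncated eigenbasis:", length(x$values), "of", x$n_total,
      "components retained (",
      sprintf("%.1f%%", 100 * x$variance_fraction_retained),
      "of variance)\n")
  invisible(x)
}
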