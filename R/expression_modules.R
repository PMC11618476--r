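# From a per-tissue expression matrix to mean-expression profiles and
# eigenvector gene-modules.  A gene-module here is a right singular vector
# (gene loadings) of the per-gene-scaled expression matrix; the retained
# modules jointly explain a chosen fraction of expression variance.

#' Mask of expressed genes
#'
#' A gene counts as expressed when its value is strictly positive in at
#' least `min_fraction` of samples (boundary inclusive).
#'
#' @param mat samples x genes non-negative matrix.
#' @param min_fraction required fraction of samples (default 0.5).
#' @return named logical vector over genes.
#' @export
filter_expressed <- function(mat, min_fraction = 0.5) {
  check_that(all(mat >= 0), "expression matrix must be non-negative")
  colMeans(mat > 0) >= min_fraction
}

#' Normalise an expression matrix
#'
#' `"vst_like"` is a simplified variance-stabilising transform,
#' `log2(x + 1)`; `"quantile"` maps every sample to the mean empirical
#' distribution across samples (delegating to
#' [limma::normalizeQuantiles()]), preserving within-sample ranks.
#'
#' @param mat samples x genes non-negative matrix.
#' @param mode `"vst_like"` (default) or `"quantile"`.
#' @return normalised matrix with the same dimnames and a
#'   `"normalisation"` attribute recording the mode.
#' @export
normalise_expression <- function(mat, mode = c("vst_like", "quantile")) {
  mode <- match.arg(mode)
  check_that(all(mat >= 0), "expression matrix must be non-negative")
  out <- switch(mode,
    vst_like = log2(mat + 1),
    quantile = t(limma::normalizeQuantiles(t(mat))))
  dimnames(out) <- dimnames(mat)
  attr(out, "normalisation") <- mode
  out
}

#' Derive eigenvector gene-modules from a normalised expression matrix
#'
#' Genes are scaled to mean 0, sd 1 (zero-variance genes are dropped with a
#' warning), the matrix is decomposed by SVD, and the leading gene-loading
#' eigenvectors are retained up to the cumulative variance fraction.  The
#' sign of each eigenvector is arbitrary; for determinism the entry with the
#' largest absolute loading is made positive (downstream, a sign flip is
#' absorbed by the sign of the module's effect size).  Mean expression per
#' gene is computed on the normalised matrix before scaling.
#'
#' @param mat samples x genes normalised matrix.
#' @param variance_fraction cumulative variance to retain, in (0, 1]
#'   (default 0.80).
#' @param tissue_id identifier stored in the result.
#' @return a `tissue_modules`: list with `tissue_id`, `genes`,
#'   `mean_expression` (named), `eigenvectors` (genes x m loadings,
#'   orthonormal columns), `eigen_variance_fractions` (all components),
#'   `variance_threshold_used`, `normalisation`.
#' @export
derive_modules <- function(mat, variance_fraction = 0.80,
                           tissue_id = "tissue") {
  check_that(variance_fraction > 0 && variance_fraction <= 1,
             "variance_fraction must be in (0, 1]")
  mean_expr <- colMeans(mat)
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped before scaling")
    mat <- mat[, sds > 0, drop = FALSE]
    mean_expr <- mean_expr[sds > 0]
  }
  S <- scale(mat)
  sv <- svd(S)
  var_frac <- sv$d^2 / sum(sv$d^2)
  k <- which(cumsum(var_frac) >= variance_fraction - 1e-12)[1]
  V <- sv$v[, seq_len(k), drop = FALSE]
  rownames(V) <- colnames(mat)
  # deterministic sign: largest-absolute-loading entry positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) V[, j] <- -V[, j]
  }
  colnames(V) <- paste0("EV", seq_len(k))
  structure(list(tissue_id = tissue_id, genes = colnames(mat),
                 mean_expression = mean_expr, eigenvectors = V,
                 eigen_variance_fractions = var_frac,
                 variance_threshold_used = variance_fraction,
                 normalisation = attr(mat, "normalisation") %||% "unknown"),
            class = "tissue_modules")
}

#' @export
print.tissue_modules <- function(x, ...) {
  cat("Tissue '", x$tissue_id, "': ", length(x$genes), " expressed genes, ",
      ncol(x$eigenvectors), " gene-modules (",
      sprintf("%.0f%%", 100 * x$variance_threshold_used),
      " variance, ", x$normalisation, " normalisation)\n", sep = "")
  invisible(x)
}

#' Full tissue processing: filter, normalise, decompose
#'
#' @param raw samples x genes non-negative matrix.
#' @param tissue_id tissue identifier.
#' @param min_fraction expressed-gene threshold (default 0.5).
#' @param mode normalisation mode (default `"vst_like"`).
#' @param variance_fraction module retention (default 0.80).
#' @return a [derive_modules()] result restricted to expressed genes.
#' @export
tissue_module_set <- function(raw, tissue_id = "tissue", min_fraction = 0.5,
                              mode = "vst_like", variance_fraction = 0.80) {
  mask <- filter_expressed(raw, min_fraction)
  check_that(sum(mask) >= 2, "fewer than 2 expressed genes")
  norm <- normalise_expression(raw[, mask, drop = FALSE], mode)
  derive_modules(norm, variance_fraction, tissue_id = tissue_id)
}
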