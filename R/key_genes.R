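# Key-gene scoring: select trait-relevant tissues, associate a tissue's
# gene-modules with the trait's gene z-scores, combine the significant
# modules into a per-gene weighted sum, standardise it against a permutation
# null, meta-analyse across tissues, and flag key genes by rare-disease
# overlap.

#' Per-gene log10 gene length covariate
#'
#' @param genes a [gene_table()].
#' @param log10 return log10 length (default `TRUE`); raw length otherwise.
#' @return named numeric vector.
#' @export
gene_lengths <- function(genes, log10 = TRUE) {
  len <- genes$end - genes$start + 1
  out <- if (log10) base::log10(len) else len
  names(out) <- genes$gene_id
  out
}

#' Default covariate matrix: shared baseline signal and gene length
#' @noRd
default_covariates <- function(shared, genes) {
  C <- NULL
  if (!is.null(shared)) {
    mm <- if (inherits(shared, "shared_signal")) shared$mean_of_means else shared
    C <- cbind(shared_signal = mm)
    rownames(C) <- names(mm)
  }
  if (!is.null(genes)) {
    gl <- gene_lengths(genes)
    if (is.null(C)) {
      C <- cbind(log10_length = gl)
      rownames(C) <- names(gl)
    } else {
      ids <- intersect(rownames(C), names(gl))
      C <- cbind(C[ids, , drop = FALSE], log10_length = gl[ids])
    }
  }
  C
}

#' Select trait-relevant tissues
#'
#' For every tissue, the trait's gene z-scores are associated with that
#' tissue's mean expression profile in the rotated regression (covariates:
#' shared baseline signal and log10 gene length).  Tissues significant after
#' Bonferroni correction over the number of tissues tested are selected.
#'
#' @param gene_z a [gene_zscores()] object (or named vector).
#' @param modulesets named list of [tissue_module_set()] objects.
#' @param basis eigenbasis from [truncate_eigen()].
#' @param shared a [mean_of_means()] result (or `NULL` to omit).
#' @param genes a [gene_table()] for the gene-length covariate (or `NULL`).
#' @param alpha family-wise level (default 0.05).
#' @return a `tissue_selection` data.frame: `tissue_id`, `beta`, `se`, `p`,
#'   `significant` (p < alpha / n tissues), ordered by p.
#' @export
select_tissues <- function(gene_z, modulesets, basis, shared = NULL,
                           genes = NULL, alpha = 0.05) {
  check_that(length(modulesets) >= 1, "need at least one tissue")
  C <- default_covariates(shared, genes)
  rows <- lapply(names(modulesets), function(tid) {
    ms <- modulesets[[tid]]
    fit <- gls_eigen(gene_z, ms$mean_expression, basis, covariates = C)
    data.frame(tissue_id = tid, beta = fit$coefficients[["x"]],
               se = fit$se[["x"]], p = fit$p[["x"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha / nrow(out)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  class(out) <- c("tissue_selection", "data.frame")
  out
}

#' Associate a tissue's gene-modules with the trait
#'
#' One rotated regression per eigenvector (module loadings as the
#' predictor), Bonferroni-corrected over the number of modules in the
#' tissue.  The significant set may be empty.
#'
#' @inheritParams select_tissues
#' @param moduleset one [tissue_module_set()].
#' @return list with `beta` (named per-module effects), `p`, `significant`
#'   (logical), `m_significant`.
#' @export
associate_eigenvectors <- function(gene_z, moduleset, basis, shared = NULL,
                                   genes = NULL, alpha = 0.05) {
  C <- default_covariates(shared, genes)
  V <- moduleset$eigenvectors
  m <- ncol(V)
  beta <- p <- numeric(m)
  for (j in seq_len(m)) {
    x <- stats::setNames(V[, j], rownames(V))
    fit <- gls_eigen(gene_z, x, basis, covariates = C)
    beta[j] <- fit$coefficients[["x"]]
    p[j] <- fit$p[["x"]]
  }
  names(beta) <- names(p) <- colnames(V)
  sig <- p < alpha / m
  list(beta = beta, p = p, significant = sig, m_significant = sum(sig))
}

#' Weighted sum of significant eigenvectors per gene
#'
#' `V_sum = sum_i V[, i] * beta[i]`: the raw key gene score.  The arbitrary
#' sign of each eigenvector is immaterial because a flip is absorbed by the
#' sign of its effect size.
#'
#' @param V genes x m matrix of significant eigenvector loadings.
#' @param beta length-m effect sizes.
#' @return named per-gene weighted sum.
#' @export
v_sum <- function(V, beta) {
  check_that(ncol(V) == length(beta), "V and beta dimensions disagree")
  check_that(ncol(V) >= 1, "need at least one eigenvector")
  drop(V %*% beta)
}

#' Permutation null for the key gene score
#'
#' Draws `n_perm` random effect vectors `beta* ~ N(0, 1)` over the same
#' significant eigenvectors and recomputes the weighted sum, giving each
#' gene a null distribution of scores.  One `beta*` matrix is shared by all
#' genes per permutation, preserving the cross-gene correlation of the null.
#' Each gene's null is summarised by its first four moments and a
#' moment-matched Johnson SU fit; when the moments fall outside the SU
#' region (common, since the construction makes the null close to normal) a
#' normal fallback is recorded.
#'
#' @param V genes x m matrix of significant eigenvector loadings.
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @param store_draws keep the genes x n_perm draw matrix (for empirical
#'   checks; default `FALSE`).
#' @return a `permutation_null`: list with `moments` (genes x 4 matrix:
#'   mean, sd, skew, kurt), `fits` (per-gene `johnson_su` or `NULL`),
#'   `fit_ok` (logical), `degenerate` (all-zero loading rows), `n_perm`,
#'   and optionally `draws`.
#' @export
permutation_null <- function(V, n_perm = 10000, seed = 1L,
                             store_draws = FALSE) {
  check_that(ncol(V) >= 1, "need at least one eigenvector")
  g <- nrow(V)
  with_seed(seed, {
    B <- matrix(stats::rnorm(ncol(V) * n_perm), ncol(V), n_perm)
    draws <- V %*% B
    mom <- t(apply(draws, 1, function(d) {
      mu <- mean(d); s <- stats::sd(d)
      if (s == 0) return(c(mean = mu, sd = 0, skew = NA, kurt = NA))
      c(mean = mu, sd = s, skew = mean((d - mu)^3) / s^3,
        kurt = mean((d - mu)^4) / s^4)
    }))
    rownames(mom) <- rownames(V)
    degenerate <- mom[, "sd"] == 0
    fits <- vector("list", g)
    names(fits) <- rownames(V)
    for (i in seq_len(g)) {
      if (degenerate[i]) next
      fits[[i]] <- johnson_su_fit(mom[i, "mean"], mom[i, "sd"],
                                  mom[i, "skew"], mom[i, "kurt"])
    }
    fit_ok <- vapply(fits, function(f) !is.null(f) && f$fit_ok, logical(1))
    out <- list(moments = mom, fits = fits, fit_ok = fit_ok,
                degenerate = degenerate, n_perm = n_perm)
    if (store_draws) out$draws <- draws
    structure(out, class = "permutation_null")
  })
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("Permutation null:", nrow(x$moments), "genes x", x$n_perm,
      "permutations;", sum(x$fit_ok), "Johnson SU fits,",
      sum(!x$fit_ok & !x$degenerate), "normal fallbacks,",
      sum(x$degenerate), "degenerate\n")
  invisible(x)
}

#' Two-sided p-value from a fitted permutation null
#' @noRd
null_pvalue <- function(v, i, null) {
  if (null$degenerate[i]) return(1)
  f <- null$fits[[i]]
  Fx <- if (!is.null(f) && f$fit_ok) pjohnson_su(v, f)
        else stats::pnorm(v, null$moments[i, "mean"], null$moments[i, "sd"])
  min(max(2 * min(Fx, 1 - Fx), .P_FLOOR), 1)
}

#' Per-gene tissue z-score from the permutation null
#'
#' Two-sided p-value of the observed weighted sum under the fitted null,
#' converted to a z-score signed by the direction of departure from the null
#' mean, so that discordant tissues can cancel in the meta-analysis.
#'
#' @param v_obs named per-gene observed [v_sum()].
#' @param null a [permutation_null()].
#' @return data.frame with `gene_id`, `v_sum`, `p`, `z`.
#' @export
tissue_z <- function(v_obs, null) {
  ids <- rownames(null$moments)
  check_that(all(ids %in% names(v_obs)), "v_obs missing genes of the null")
  p <- vapply(seq_along(ids),
              function(i) null_pvalue(v_obs[[ids[i]]], i, null), numeric(1))
  z <- stats::qnorm(p / 2, lower.tail = FALSE) *
    sign(v_obs[ids] - null$moments[, "mean"])
  z[p >= 1] <- 0
  data.frame(gene_id = ids, v_sum = unname(v_obs[ids]), p = p,
             z = unname(z), stringsAsFactors = FALSE)
}

#' Stouffer meta-analysis of tissue key gene scores
#'
#' `Z_meta = sum(Z_tissue) / sqrt(k)` with equal weights; a gene missing
#' from some tissues is combined over the tissues where it is present, with
#' its own k.  Significance is Bonferroni over the genes tested.
#'
#' @param Z_all genes x tissues matrix of tissue z-scores (NA where a gene
#'   is absent from a tissue).
#' @param alpha family-wise level for the significance flag (default 0.05).
#' @return data.frame: `gene_id`, `z_meta`, `p_meta`, `k`, `significant`.
#' @export
meta_analyse <- function(Z_all, alpha = 0.05) {
  check_that(is.matrix(Z_all) && ncol(Z_all) >= 1, "need a genes x k matrix")
  k <- rowSums(!is.na(Z_all))
  if (any(k < ncol(Z_all)))
    message(sum(k < ncol(Z_all)), " gene(s) missing from some tissues; ",
            "meta over available tissues")
  z_meta <- rowSums(Z_all, na.rm = TRUE) / sqrt(pmax(k, 1))
  z_meta[k == 0] <- NA
  p_meta <- 2 * stats::pnorm(-abs(z_meta))
  n_tested <- sum(k > 0)
  data.frame(gene_id = rownames(Z_all), z_meta = z_meta, p_meta = p_meta,
             k = k, significant = !is.na(p_meta) & p_meta < alpha / n_tested,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag key genes by rare-disease overlap
#'
#' A key gene is a gene with a significant meta key gene score *and* a known
#' annotation to at least one of the supplied phenotype-matched rare-disease
#' terms.
#'
#' @param meta a [meta_analyse()] data.frame.
#' @param disease_sets a [gene_set_collection()] of phenotype-matched terms
#'   (which terms match the trait is the caller's choice).
#' @return the data.frame with an added logical `key_gene` column.
#' @export
flag_key_genes <- function(meta, disease_sets) {
  annotated <- unique(unlist(disease_sets$members))
  meta$key_gene <- meta$significant & meta$gene_id %in% annotated
  meta
}

#' Run the full key-gene prioritisation for one trait
#'
#' Composes the pipeline: tissue selection, per-tissue module association,
#' weighted-sum key gene scores standardised against a permutation null,
#' Stouffer meta-analysis across the selected tissues, and (optionally)
#' rare-disease key-gene flagging.
#'
#' @inheritParams select_tissues
#' @param disease_sets optional [gene_set_collection()] of phenotype-matched
#'   rare-disease terms.
#' @param n_perm permutations for the per-tissue null (default 10000).
#' @param seed integer seed.
#' @param multi_tissue_id optional name of a multi-tissue module set that is
#'   scored but never enters the meta-analysis.
#' @return a `key_gene_result`: list with `tissue_selection`, `tissues`
#'   (per selected tissue: association, null summary, z table, `status`),
#'   `Z_all` (genes x k matrix), `meta` (data.frame incl. `key_gene` if
#'   disease sets given), `status` (`"ok"` or `"no_significant_tissue"`).
#' @export
key_gene_analysis <- function(gene_z, modulesets, basis, shared = NULL,
                              genes = NULL, disease_sets = NULL,
                              alpha = 0.05, n_perm = 10000, seed = 1L,
                              multi_tissue_id = NULL) {
  sel <- select_tissues(gene_z, modulesets, basis, shared = shared,
                        genes = genes, alpha = alpha)
  picked <- sel$tissue_id[sel$significant]
  res <- list(tissue_selection = sel, tissues = list(), Z_all = NULL,
              meta = NULL, status = "ok")
  class(res) <- "key_gene_result"
  if (length(picked) == 0L) {
    res$status <- "no_significant_tissue"
    message("no tissue passed Bonferroni selection; meta-analysis skipped")
    return(res)
  }
  z_tabs <- list()
  for (tid in picked) {
    ms <- modulesets[[tid]]
    assoc <- associate_eigenvectors(gene_z, ms, basis, shared = shared,
                                    genes = genes, alpha = alpha)
    entry <- list(association = assoc, status = "ok")
    if (assoc$m_significant == 0L) {
      entry$status <- "no_significant_module"
      res$tissues[[tid]] <- entry
      next
    }
    V <- ms$eigenvectors[, assoc$significant, drop = FALSE]
    vs <- v_sum(V, assoc$beta[assoc$significant])
    null <- permutation_null(V, n_perm = n_perm, seed = seed)
    zt <- tissue_z(vs, null)
    entry$null <- null
    entry$z <- zt
    res$tissues[[tid]] <- entry
    if (is.null(multi_tissue_id) || tid != multi_tissue_id)
      z_tabs[[tid]] <- zt
  }
  if (length(z_tabs) == 0L) {
    res$status <- "no_significant_module"
    return(res)
  }
  all_genes <- sort(unique(unlist(lapply(z_tabs, `[[`, "gene_id"))))
  Z_all <- matrix(NA_real_, length(all_genes), length(z_tabs),
                  dimnames = list(all_genes, names(z_tabs)))
  for (tid in names(z_tabs))
    Z_all[z_tabs[[tid]]$gene_id, tid] <- z_tabs[[tid]]$z
  res$Z_all <- Z_all
  res$meta <- meta_analyse(Z_all, alpha = alpha)
  if (!is.null(disease_sets)) res$meta <- flag_key_genes(res$meta, disease_sets)
  res
}

#' @export
print.key_gene_result <- function(x, ...) {
  cat("Key-gene analysis\n")
  cat("  tissues tested:", nrow(x$tissue_selection),
      " selected:", sum(x$tissue_selection$significant), "\n")
  if (!is.null(x$meta)) {
    cat("  genes meta-analysed:", nrow(x$meta),
        " significant:", sum(x$meta$significant), "\n")
    if (!is.null(x$meta$key_gene))
      cat("  key genes (significant + rare-disease annotated):",
          sum(x$meta$key_gene), "\n")
  } else cat("  status:", x$status, "\n")
  invisible(x)
}

#' @export
summary.key_gene_result <- function(object, n = 10, ...) {
  print(object)
  if (!is.null(object$meta)) {
    cat("\nTop genes by |meta z|:\n")
    ord <- order(-abs(object$meta$z_meta))
    print(utils::head(object$meta[ord, ], n), row.names = FALSE)
  }
  invisible(object)
}

#' @export
as.data.frame.key_gene_result <- function(x, ...) {
  check_that(!is.null(x$meta), "no meta-analysis result available")
  out <- x$meta
  if (!is.null(x$Z_all)) {
    zt <- as.data.frame(x$Z_all)
    names(zt) <- paste0("z_", names(zt))
    out <- cbind(out, zt[match(out$gene_id, rownames(x$Z_all)), ,
                         drop = FALSE])
  }
  rownames(out) <- NULL
  out
}
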