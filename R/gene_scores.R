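# Aggregation of variant-level p-values into per-gene z-scores over a
# +/- 25 kb window around the gene body, accounting for the LD structure of
# the window.  The statistic is a sum of squared variant z-scores whose null
# distribution is a weighted sum of 1-df chi-squares with weights equal to
# the eigenvalues of the window's LD matrix.

#' Collect the variants in a gene's window
#'
#' @param gene one row of a [gene_table()] (or a list with `chromosome`,
#'   `start`, `end`).
#' @param variants a `variant_table`.
#' @param window_bp bases added up- and downstream of the gene body
#'   (default 25000); both window ends are inclusive.
#' @return the subset of `variants` with position in
#'   `[start - window_bp, end + window_bp]` on the gene's chromosome
#'   (possibly empty).
#' @export
collect_window_variants <- function(gene, variants, window_bp = 25000) {
  sel <- variants$chromosome == gene$chromosome &
    variants$position >= gene$start - window_bp &
    variants$position <= gene$end + window_bp
  variants[sel, , drop = FALSE]
}

#' LD-aware gene-level p-value from window variant p-values
#'
#' Each two-sided variant p-value is converted to a direction-free z,
#' `z_i = qnorm(1 - p_i / 2)`, and the gene statistic is `T = sum(z_i^2)`.
#' Under the null, the vector of variant z-scores is multivariate normal
#' with correlation equal to the window LD matrix, so `T` is distributed as
#' `sum(lambda_j * chisq_1)` with `lambda_j` the LD eigenvalues (negative
#' eigenvalues from a noisy estimate are clipped to zero).  The tail
#' probability is computed by a Satterthwaite moment-matched gamma by
#' default, which is exact whenever the eigenvalues are equal (a single
#' variant, perfect LD, or fully independent variants), or by numerical
#' inversion of the characteristic function (Imhof's method) when
#' `method = "inversion"`.
#'
#' @param p_values variant p-values in the window (each in (0, 1]).
#' @param ld window LD matrix (variant x variant correlation); may be
#'   omitted for a single variant.
#' @param method `"satterthwaite"` (default) or `"inversion"`.
#' @return the gene-level p-value in (0, 1].
#' @export
gene_pvalue <- function(p_values, ld = NULL,
                        method = c("satterthwaite", "inversion")) {
  method <- match.arg(method)
  m <- length(p_values)
  check_that(m >= 1L, "at least one variant required")
  check_that(all(p_values > 0 & p_values <= 1), "p-values must be in (0, 1]")
  if (is.null(ld)) {
    check_that(m == 1L, "ld matrix required for more than one variant")
    ld <- matrix(1, 1, 1)
  }
  lambda <- eigen(ld, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  z <- stats::qnorm(p_values / 2, lower.tail = FALSE)
  weighted_chisq_tail(sum(z^2), lambda, method = method)
}

#' Tail probability of a weighted sum of 1-df chi-squares
#'
#' @param q observed statistic.
#' @param lambda non-negative weights (eigenvalues).
#' @param method `"satterthwaite"` for the moment-matched gamma,
#'   `"inversion"` for Imhof's characteristic-function integral.
#' @return `P(sum(lambda_j chisq_1) >= q)`, clamped to (0, 1].
#' @export
weighted_chisq_tail <- function(q, lambda,
                                method = c("satterthwaite", "inversion")) {
  method <- match.arg(method)
  lambda <- lambda[lambda > 0]
  check_that(length(lambda) > 0L, "all eigenvalues are zero")
  if (method == "satterthwaite") {
    s1 <- sum(lambda); s2 <- sum(lambda^2)
    shape <- s1^2 / (2 * s2)             # matches mean s1, variance 2*s2
    scl <- 2 * s2 / s1
    p <- stats::pgamma(q, shape = shape, scale = scl, lower.tail = FALSE)
  } else {
    # Imhof (1961): P(Q >= q) = 1/2 + (1/pi) * Int_0^inf sin(theta(u))/(u rho(u)) du
    theta <- function(u) 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- function(u)
      exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    f <- function(u) sin(theta(u)) / (u * rho(u))
    # the integrand envelope decays as u^-(m/2 + 1); truncate where it is
    # negligible and let the quadrature resolve the oscillations
    m_pos <- length(lambda)
    upper <- (1e12 / prod(sqrt(lambda)))^(1 / (m_pos / 2 + 1))
    int <- stats::integrate(f, 0, upper, rel.tol = 1e-7, abs.tol = 1e-12,
                            subdivisions = 100000L, stop.on.error = FALSE)
    p <- 0.5 + int$value / pi
  }
  min(max(p, .P_FLOOR), 1)
}

#' Convert gene p-values to gene z-scores
#'
#' `z = qnorm(1 - p)`: strictly decreasing in p, zero at p = 0.5.  The sign
#' of a gene z-score carries no GWAS effect direction — it only encodes how
#' surprising the window's aggregate association is.
#'
#' @param p per-gene p-values in (0, 1], named by gene id.
#' @return named numeric vector of z-scores.
#' @export
pvalues_to_z <- function(p) {
  check_that(all(p > 0 & p <= 1), "p-values must be in (0, 1]")
  stats::qnorm(floor_p(p), lower.tail = FALSE)
}

#' Construct a gene z-score set for one trait
#'
#' @param z named per-gene z-scores.
#' @param trait_id trait identifier.
#' @param trait_class one of the eight trait classes (`"immune"`,
#'   `"cancer"`, `"skeletal"`, `"blood composition"`, `"neuro"`,
#'   `"cardiovascular"`, `"metabolic"`, `"other"`).
#' @return a `gene_zscores` object.
#' @export
gene_zscores <- function(z, trait_id = "trait", trait_class = "other") {
  classes <- c("immune", "cancer", "skeletal", "blood composition", "neuro",
               "cardiovascular", "metabolic", "other")
  check_that(trait_class %in% classes,
             paste("trait_class must be one of:", paste(classes, collapse = ", ")))
  check_that(!is.null(names(z)) && all(nzchar(names(z))),
             "z must be named by gene id")
  check_that(all(is.finite(z)), "gene z-scores must be finite")
  structure(list(trait_id = trait_id, trait_class = trait_class,
                 z = z, genes = names(z)),
            class = "gene_zscores")
}

#' @export
print.gene_zscores <- function(x, ...) {
  cat("Gene z-scores for trait '", x$trait_id, "' (class: ", x$trait_class,
      "), ", length(x$z), " genes\n", sep = "")
  invisible(x)
}

#' Precompute per-gene windows and LD eigenvalues from a panel
#'
#' For repeated scoring (e.g. thousands of null GWASs on the same panel) the
#' window membership and LD eigendecomposition per gene are computed once.
#'
#' @param genes a [gene_table()].
#' @param panel a [simulate_genotypes()] panel (or any list with `dosage`
#'   and `variants`).
#' @param window_bp window half-width (default 25000).
#' @return a `gene_windows` object: list with per-gene variant indices and
#'   LD eigenvalues; genes with no window variants are dropped (recorded in
#'   the `dropped` element).
#' @export
gene_ld_windows <- function(genes, panel, window_bp = 25000) {
  variants <- panel$variants
  R_all <- NULL
  idx_list <- vector("list", nrow(genes))
  names(idx_list) <- genes$gene_id
  for (g in seq_len(nrow(genes))) {
    sel <- which(variants$chromosome == genes$chromosome[g] &
                 variants$position >= genes$start[g] - window_bp &
                 variants$position <= genes$end[g] + window_bp)
    idx_list[[g]] <- sel
  }
  keep <- vapply(idx_list, length, integer(1)) > 0L
  dropped <- genes$gene_id[!keep]
  if (length(dropped))
    message(length(dropped), " gene(s) with no window variants excluded")
  idx_list <- idx_list[keep]
  eig_list <- lapply(idx_list, function(sel) {
    R <- stats::cor(panel$dosage[, sel, drop = FALSE])
    R[!is.finite(R)] <- 0; diag(R) <- 1
    pmax(eigen(R, symmetric = TRUE, only.values = TRUE)$values, 0)
  })
  structure(list(index = idx_list, eigenvalues = eig_list,
                 dropped = dropped, window_bp = window_bp),
            class = "gene_windows")
}

#' Score genes for one or many traits from variant p-values
#'
#' Vectorised scoring against precomputed [gene_ld_windows()]: for each gene
#' and trait the window statistic is formed and converted to a p-value and a
#' z-score.
#'
#' @param windows a [gene_ld_windows()] object.
#' @param p_matrix variants x traits matrix of p-values (a single trait may
#'   be passed as a vector), rows aligned with the panel's variant table.
#' @param method tail method passed to [weighted_chisq_tail()].
#' @return list with `p` and `z`: genes x traits matrices (gene ids as
#'   rownames).
#' @export
score_genes <- function(windows, p_matrix, method = "satterthwaite") {
  if (is.null(dim(p_matrix))) p_matrix <- matrix(p_matrix, ncol = 1)
  Z2 <- stats::qnorm(pmin(pmax(p_matrix, .P_FLOOR), 1) / 2,
                     lower.tail = FALSE)^2
  n_genes <- length(windows$index)
  P <- matrix(NA_real_, n_genes, ncol(p_matrix),
              dimnames = list(names(windows$index), colnames(p_matrix)))
  for (g in seq_len(n_genes)) {
    Tg <- colSums(Z2[windows$index[[g]], , drop = FALSE])
    lam <- windows$eigenvalues[[g]]
    if (method == "satterthwaite") {
      s1 <- sum(lam); s2 <- sum(lam^2)
      P[g, ] <- pmin(pmax(stats::pgamma(Tg, shape = s1^2 / (2 * s2),
                                        scale = 2 * s2 / s1,
                                        lower.tail = FALSE), .P_FLOOR), 1)
    } else {
      P[g, ] <- vapply(Tg, weighted_chisq_tail, numeric(1), lambda = lam,
                       method = method)
    }
  }
  list(p = P, z = stats::qnorm(P, lower.tail = FALSE))
}

#' Full variant-to-gene scoring for a single GWAS
#'
#' Convenience wrapper: builds windows from the panel, restricts the GWAS to
#' variants present in the panel, and returns a [gene_zscores()] object.
#'
#' @param gwas a `variant_table` with p-values.
#' @param genes a [gene_table()].
#' @param panel a genotype panel providing the LD reference.
#' @param window_bp window half-width (default 25000).
#' @param trait_id,trait_class metadata for the resulting score set.
#' @param method tail method.
#' @return a [gene_zscores()] object covering every gene with at least one
#'   window variant.
#' @export
score_gwas <- function(gwas, genes, panel, window_bp = 25000,
                       trait_id = "trait", trait_class = "other",
                       method = "satterthwaite") {
  m <- match(panel$variants$variant_id, gwas$variant_id)
  check_that(any(!is.na(m)), "no GWAS variants match the panel")
  pvec <- rep(NA_real_, nrow(panel$variants))
  pvec[!is.na(m)] <- gwas$p_value[m[!is.na(m)]]
  # restrict the panel windows to variants with a p-value
  sub_panel <- list(dosage = panel$dosage[, !is.na(pvec), drop = FALSE],
                    variants = panel$variants[!is.na(pvec), , drop = FALSE])
  windows <- gene_ld_windows(genes, sub_panel, window_bp = window_bp)
  sc <- score_genes(windows, pvec[!is.na(pvec)], method = method)
  gene_zscores(stats::setNames(sc$z[, 1], rownames(sc$z)),
               trait_id = trait_id, trait_class = trait_class)
}
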