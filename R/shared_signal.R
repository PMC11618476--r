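# Cross-trait shared signal: certain genes attract GWAS associations for
# almost any trait (dense regulatory regions, long genes, strong LD).  The
# per-gene average z-score over many traits captures this baseline, and is
# used as a covariate downstream; its enrichment analysis residualises it on
# LD extent and local gene density first.

#' Two-stage "mean of means" average gene z-score
#'
#' The per-gene average is computed in two stages so that over-represented
#' trait classes do not dominate: first the mean per trait class, then the
#' unweighted mean over the classes present.  A gene missing from every
#' trait of a class is simply absent from that class's mean; its outer mean
#' runs over the classes where it is present.
#'
#' @param traits list of [gene_zscores()] objects (or named numeric vectors
#'   with a `trait_class` attribute).
#' @return a `shared_signal`: list with `mean_of_means` (named per-gene
#'   vector), `class_means` (genes x classes matrix), `classes_present`.
#' @export
mean_of_means <- function(traits) {
  check_that(length(traits) >= 1, "need at least one trait")
  zs <- lapply(traits, function(tr) {
    if (inherits(tr, "gene_zscores")) tr$z else tr
  })
  cls <- vapply(traits, function(tr) {
    if (inherits(tr, "gene_zscores")) tr$trait_class
    else attr(tr, "trait_class") %||% "other"
  }, character(1))
  genes <- unique(unlist(lapply(zs, names)))
  check_that(!is.null(genes), "traits must carry gene names")
  classes <- unique(cls)
  class_means <- matrix(NA_real_, length(genes), length(classes),
                        dimnames = list(genes, classes))
  for (cl in classes) {
    Z <- vapply(zs[cls == cl], function(z) z[genes], numeric(length(genes)))
    class_means[, cl] <- rowMeans(matrix(Z, nrow = length(genes)), na.rm = TRUE)
  }
  missing_any <- apply(class_means, 1, function(r) any(is.nan(r) | is.na(r)))
  if (any(missing_any))
    message(sum(missing_any), " gene(s) absent from all traits of some ",
            "class; their outer mean uses the classes present")
  mm <- rowMeans(class_means, na.rm = TRUE)
  structure(list(mean_of_means = mm, class_means = class_means,
                 classes_present = classes),
            class = "shared_signal")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.shared_signal <- function(x, ...) {
  cat("Shared baseline signal over", length(x$classes_present),
      "trait class(es),", length(x$mean_of_means), "genes\n")
  invisible(x)
}

#' Local gene density
#'
#' Number of other genes whose span intersects the window
#' `[start - window_bp, end + window_bp]` (both boundaries inclusive).  The
#' gene itself is excluded: its own presence is constant and uninformative.
#'
#' @param genes a [gene_table()].
#' @param window_bp window half-width around the gene span (default 250000).
#' @return named integer vector of counts.
#' @export
gene_density <- function(genes, window_bp = 250000) {
  out <- integer(nrow(genes))
  names(out) <- genes$gene_id
  for (chr in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == chr, , drop = FALSE]
    lo <- g$start - window_bp; hi <- g$end + window_bp
    for (i in seq_len(nrow(g))) {
      hit <- g$start <= hi[i] & g$end >= lo[i]
      out[g$gene_id[i]] <- sum(hit) - 1L   # minus self
    }
  }
  out
}

#' Per-gene mean LD score
#'
#' The LD score of a variant is the sum of its squared correlations with all
#' variants within `variant_window_bp`, including itself.  A gene's LD score
#' is the mean over the variants in its own window.  Scores are computed
#' from the supplied genotype panel, so no external download is needed.
#'
#' @param genes a [gene_table()].
#' @param panel a genotype panel.
#' @param window_bp gene window half-width (default 25000).
#' @param variant_window_bp half-width of the per-variant LD-score window
#'   (default 25000).
#' @return named numeric vector (NA for genes without window variants).
#' @export
ld_scores <- function(genes, panel, window_bp = 25000,
                      variant_window_bp = 25000) {
  v <- panel$variants
  # per-variant LD scores, computed per chromosome
  score <- numeric(nrow(v))
  for (chr in unique(v$chromosome)) {
    sel <- which(v$chromosome == chr)
    pos <- v$position[sel]
    G <- panel$dosage[, sel, drop = FALSE]
    R2 <- suppressWarnings(stats::cor(G))^2
    R2[!is.finite(R2)] <- 0
    within <- abs(outer(pos, pos, "-")) <= variant_window_bp
    diag(R2) <- 1                        # a variant always counts itself
    score[sel] <- rowSums(R2 * within)
  }
  out <- rep(NA_real_, nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    sel <- v$chromosome == genes$chromosome[i] &
      v$position >= genes$start[i] - window_bp &
      v$position <= genes$end[i] + window_bp
    if (any(sel)) out[i] <- mean(score[sel])
  }
  out
}

#' Residualise the average gene z-score on LD extent and gene density
#'
#' Fits an ordinary linear model of the shared signal on the per-gene mean
#' LD score and the local gene density (with intercept) and returns the
#' residuals, so the enrichment of the "average GWAS" signal can be studied
#' net of these technical drivers.
#'
#' @param signal a [mean_of_means()] result or named numeric vector.
#' @param ld_score named per-gene mean LD score.
#' @param density named per-gene density from [gene_density()].
#' @param top_k how many top-residual genes to report (default 500).
#' @return list with `residuals` (named), `top` (gene ids of the `top_k`
#'   largest residuals), `r_squared` of the fit, and the fitted `model`.
#'   Zero-variance covariates are dropped with a warning.
#' @export
residualise_average <- function(signal, ld_score, density, top_k = 500) {
  y <- if (inherits(signal, "shared_signal")) signal$mean_of_means else signal
  ids <- Reduce(intersect, list(names(y), names(ld_score), names(density)))
  check_that(length(ids) > 2, "need > 2 genes shared across inputs")
  df <- data.frame(y = y[ids], ld_score = ld_score[ids],
                   density = as.numeric(density[ids]))
  keep <- c(ld_score = stats::sd(df$ld_score) > 0,
            density = stats::sd(df$density) > 0)
  if (!all(keep))
    warning("zero-variance covariate(s) dropped: ",
            paste(names(keep)[!keep], collapse = ", "))
  covs <- names(keep)[keep]
  form <- stats::as.formula(
    paste("y ~", if (length(covs)) paste(covs, collapse = " + ") else "1"))
  fit <- stats::lm(form, data = df)
  res <- stats::setNames(stats::residuals(fit), ids)
  top <- names(sort(res, decreasing = TRUE))[seq_len(min(top_k, length(res)))]
  list(residuals = res, top = top,
       r_squared = summary(fit)$r.squared, model = fit)
}
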