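# Generators for fully synthetic study inputs: LD-block genotypes, null GWAS
# traits, expression matrices with planted co-expression modules, and a
# composite end-to-end fixture with a planted key-gene architecture.  Every
# generator is a pure function of (parameters, seed).

# Correlation of two allele indicators 1(Z > t) under a latent bivariate
# normal with correlation rho: (P11 - p^2) / (p (1 - p)).
threshold_corr <- function(rho, t) {
  p <- stats::pnorm(t, lower.tail = FALSE)
  if (rho >= 1) return(1)
  p11 <- stats::integrate(function(x)
    stats::dnorm(x) * stats::pnorm((rho * x - t) / sqrt(1 - rho^2)),
    t, Inf, rel.tol = 1e-9)$value
  (p11 - p^2) / (p * (1 - p))
}

# Latent AR(1) coefficient that yields a target dosage correlation between
# adjacent variants after thresholding at t.
latent_rho_for <- function(target, t) {
  if (threshold_corr(1 - 1e-9, t) <= target) return(1 - 1e-9)
  stats::uniroot(function(r) threshold_corr(r, t) - target,
                 lower = 0, upper = 1 - 1e-9, tol = 1e-6)$root
}

#' Simulate an LD-block genotype reference panel
#'
#' Genotypes are generated per block from an AR(1) latent Gaussian: two
#' independent latent haplotypes are drawn with autocorrelation between
#' adjacent variants, each thresholded at the allele-frequency quantile, and
#' summed to a dosage in {0, 1, 2}.  Thresholding a Gaussian attenuates
#' correlation, so the latent autocorrelation is calibrated numerically such
#' that the *realized dosage* correlation between adjacent variants matches
#' the requested `rho`.  Blocks are mutually independent, so LD never
#' crosses a block boundary — emulating the block structure of a real
#' reference panel without any download.
#'
#' @param n_samples number of individuals.
#' @param blocks data.frame (or list coercible to one) with columns
#'   `n_variants` and `rho` (0 <= rho < 1), one row per LD block; optional
#'   column `chromosome` (default all `"1"`).
#' @param maf_range length-2 numeric in (0, 0.5]; one minor allele frequency
#'   per block is drawn uniformly from this range (variants in tight LD
#'   share frequencies, and a common threshold keeps the requested LD
#'   attainable).
#' @param seed integer seed; the same seed reproduces the panel bit for bit.
#' @param variant_spacing_bp distance between adjacent variants in a block.
#' @param block_gap_bp gap between the last variant of one block and the
#'   first of the next (same chromosome).
#' @return a `genotype_panel`: list with `dosage` (samples x variants matrix),
#'   `variants` (data.frame: `variant_id`, `chromosome`, `position`, `maf`,
#'   `block`), `n_samples`.
#' @export
simulate_genotypes <- function(n_samples, blocks, maf_range = c(0.05, 0.5),
                               seed = 1L, variant_spacing_bp = 2000L,
                               block_gap_bp = 1e6) {
  blocks <- as.data.frame(blocks)
  check_that(all(c("n_variants", "rho") %in% names(blocks)),
             "'blocks' needs columns n_variants and rho")
  check_that(all(blocks$rho >= 0 & blocks$rho < 1), "each rho must be in [0, 1)")
  check_that(length(maf_range) == 2L && maf_range[1] > 0 && maf_range[2] <= 0.5
             && maf_range[1] <= maf_range[2],
             "maf_range must lie in (0, 0.5]")
  if (is.null(blocks$chromosome)) blocks$chromosome <- "1"
  blocks$chromosome <- as.character(blocks$chromosome)

  with_seed(seed, {
    dosage_list <- vector("list", nrow(blocks))
    meta_list <- vector("list", nrow(blocks))
    pos_next <- stats::setNames(rep(1L, length(unique(blocks$chromosome))),
                                unique(blocks$chromosome))
    for (b in seq_len(nrow(blocks))) {
      m <- blocks$n_variants[b]
      rho <- blocks$rho[b]
      chr <- blocks$chromosome[b]
      maf <- rep(stats::runif(1, maf_range[1], maf_range[2]), m)
      thr <- stats::qnorm(1 - maf)
      rho_lat <- if (rho > 0) latent_rho_for(rho, thr[1]) else 0
      # two latent haplotypes with AR(1) structure along the block
      hap <- function() {
        z <- matrix(stats::rnorm(n_samples * m), n_samples, m)
        if (m > 1L && rho_lat > 0)
          for (j in 2:m) z[, j] <- rho_lat * z[, j - 1] +
              sqrt(1 - rho_lat^2) * z[, j]
        z
      }
      a1 <- sweep(hap(), 2, thr, ">")
      a2 <- sweep(hap(), 2, thr, ">")
      dosage_list[[b]] <- a1 + a2
      pos <- pos_next[chr] + seq.int(0L, by = variant_spacing_bp,
                                     length.out = m)
      pos_next[chr] <- pos[m] + block_gap_bp
      meta_list[[b]] <- data.frame(
        variant_id = sprintf("v%s_%d", chr, pos),
        chromosome = chr, position = as.integer(pos), maf = maf, block = b,
        stringsAsFactors = FALSE)
    }
    dosage <- do.call(cbind, dosage_list)
    variants <- do.call(rbind, meta_list)
    colnames(dosage) <- variants$variant_id
    structure(list(dosage = dosage, variants = variants,
                   n_samples = n_samples),
              class = "genotype_panel")
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", x$n_samples, "samples x", nrow(x$variants),
      "variants in", length(unique(x$variants$block)), "LD block(s)\n")
  invisible(x)
}

#' Simulate null GWAS traits on a genotype panel
#'
#' Each trait is a phenotype drawn from a standard normal, independent of all
#' genotypes; per-variant association p-values come from the simple linear
#' regression of phenotype on dosage.  Because the phenotypes are pure noise,
#' any correlation between the resulting gene-level scores reflects only the
#' LD structure of the panel — which is exactly what these nulls are used to
#' measure.
#'
#' @param panel a [simulate_genotypes()] panel.
#' @param n_traits number of null traits (>= 1).
#' @param seed integer seed.
#' @return a `null_gwas_set`: list with `p` (variants x traits matrix of
#'   p-values), `variants` (the panel's variant table), `n_traits`.
#'   Monomorphic variants get p = 1 (with a message).
#' @export
simulate_null_gwas <- function(panel, n_traits, seed = 1L) {
  check_that(n_traits >= 1, "n_traits must be >= 1")
  G <- panel$dosage
  n <- nrow(G)
  sds <- apply(G, 2, stats::sd)
  mono <- sds == 0
  if (any(mono))
    message(sum(mono), " monomorphic variant(s): p set to 1")
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * n_traits), n, n_traits)
    Yc <- scale(Y)                       # columns mean 0, sd 1
    Gc <- scale(G[, !mono, drop = FALSE])
    # Pearson r between each variant and each trait, then the regression t
    r <- crossprod(Gc, Yc) / (n - 1)
    r <- pmin(pmax(r, -1), 1)
    tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    P <- matrix(1, ncol(G), n_traits,
                dimnames = list(colnames(G),
                                paste0("null_trait_", seq_len(n_traits))))
    P[!mono, ] <- p
    structure(list(p = P, variants = panel$variants, n_traits = n_traits),
              class = "null_gwas_set")
  })
}

#' Extract one null trait as a variant table
#'
#' @param nulls a [simulate_null_gwas()] result.
#' @param trait trait index.
#' @return a `variant_table` with the trait's p-values.
#' @export
null_gwas_variants <- function(nulls, trait = 1L) {
  df <- nulls$variants
  df$p_value <- nulls$p[, trait]
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Simulate an expression matrix with planted co-expression modules
#'
#' Gene expression follows a latent-factor model on the log scale: each
#' planted module has one latent factor, and every gene in the module equals
#' `loading * factor + noise`.  Genes outside all modules are pure noise.
#' The leading SVD components of the (scaled) matrix therefore recover the
#' planted modules.
#'
#' @param n_samples,n_genes matrix dimensions.
#' @param modules data.frame with columns `size` and `loading`, one row per
#'   planted module; sizes must sum to at most `n_genes`.  Modules occupy
#'   consecutive gene columns starting at gene 1.
#' @param noise_sd standard deviation of the additive noise.
#' @param seed integer seed.
#' @param counts_like if `TRUE` the Gaussian matrix is exponentiated (base 2)
#'   and shifted so all values are non-negative "counts-like" intensities.
#' @param baseline optional per-gene baseline added to every sample (length
#'   `n_genes`); defaults to 0.
#' @return a `planted_expression`: list with `matrix` (samples x genes,
#'   dimnames set), `modules` (list of gene-id vectors), `loadings` (per-gene
#'   loading, 0 outside modules), `factors` (samples x modules).
#' @export
simulate_expression <- function(n_samples, n_genes, modules, noise_sd = 1,
                                seed = 1L, counts_like = FALSE,
                                baseline = NULL) {
  modules <- as.data.frame(modules)
  if (nrow(modules)) {
    check_that(all(c("size", "loading") %in% names(modules)),
               "'modules' needs columns size and loading")
    check_that(sum(modules$size) <= n_genes,
               "module sizes sum to more than n_genes")
  }
  if (is.null(baseline)) baseline <- numeric(n_genes)
  check_that(length(baseline) == n_genes, "baseline must have length n_genes")
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  with_seed(seed, {
    X <- matrix(stats::rnorm(n_samples * n_genes, sd = noise_sd),
                n_samples, n_genes)
    loadings <- numeric(n_genes)
    member_list <- list()
    FF <- NULL
    if (nrow(modules)) {
      FF <- matrix(stats::rnorm(n_samples * nrow(modules)),
                   n_samples, nrow(modules))
      at <- 1L
      for (m in seq_len(nrow(modules))) {
        idx <- seq.int(at, length.out = modules$size[m])
        at <- at + modules$size[m]
        X[, idx] <- X[, idx] + FF[, m] %o% rep(modules$loading[m],
                                               length(idx))
        loadings[idx] <- modules$loading[m]
        member_list[[m]] <- gene_ids[idx]
      }
    }
    X <- sweep(X, 2, baseline, "+")
    if (counts_like) X <- 2^X - min(2^X)  # non-negative, monotone in X
    dimnames(X) <- list(sprintf("sample_%04d", seq_len(n_samples)), gene_ids)
    names(loadings) <- gene_ids
    structure(list(matrix = X, modules = member_list, loadings = loadings,
                   factors = FF),
              class = "planted_expression")
  })
}

#' Simulate a gene-gene correlation fixture with strong LD-driven structure
#'
#' Builds a genotype panel in which groups of genes share a single high-LD
#' variant block (their score windows all cover the same block), runs null
#' GWASs, scores the genes and estimates the gene-gene correlation matrix.
#' Genes sharing a block end up strongly correlated — the structure the
#' null-calibration experiment needs.
#'
#' @param n_blocks number of independent LD blocks (default 60).
#' @param genes_per_block genes sharing each block (default 6).
#' @param variants_per_block variants per block (default 12).
#' @param rho within-block LD (default 0.95).
#' @param n_samples panel samples (default 600).
#' @param n_null null GWAS traits for the correlation estimate
#'   (default 500).
#' @param seed integer seed.
#' @return list with `panel`, `genes` (gene_table), `null_z` (genes x
#'   traits z matrix) and `omega` (an [build_omega()] result).
#' @export
simulate_omega_fixture <- function(n_blocks = 60, genes_per_block = 6,
                                   variants_per_block = 12, rho = 0.95,
                                   n_samples = 600, n_null = 500,
                                   seed = 1L) {
  blocks <- data.frame(n_variants = variants_per_block, rho = rho)
  blocks <- blocks[rep(1L, n_blocks), ]
  panel <- simulate_genotypes(n_samples, blocks, seed = seed)
  v <- panel$variants
  gdf <- do.call(rbind, lapply(split(v, v$block), function(d) {
    b <- d$block[1]
    do.call(rbind, lapply(seq_len(genes_per_block), function(k)
      data.frame(gene_id = sprintf("g%03d_%d", b, k),
                 chromosome = d$chromosome[1],
                 start = min(d$position) + (k - 1L) * 2000L,
                 end = min(d$position) + (k - 1L) * 2000L + 5000L,
                 strand = "+", biotype = "protein_coding",
                 stringsAsFactors = FALSE)))
  }))
  genes <- gene_table(gdf, stats::setNames(max(v$position) + 1e7, "1"))
  nulls <- simulate_null_gwas(panel, n_null, seed = seed + 1L)
  w <- gene_ld_windows(genes, panel)
  z <- score_genes(w, nulls$p)$z
  list(panel = panel, genes = genes, null_z = z,
       omega = build_omega(z, genes))
}

#' Simulate a complete key-gene study fixture
#'
#' Builds every input of the pipeline around a planted "key gene"
#' architecture.  The causal tissue's expression follows a broad factor
#' model: `n_factors` co-expression factors each load with small random
#' weights on all genes, but a designated set of core genes loads positively
#' and consistently on *every* factor — the hub-like behaviour expected of
#' core genes under an omnigenic architecture.  The trait's gene z-scores are
#' then built as `effect x (summed module loadings) + noise`, so trait signal
#' flows through the very modules the causal tissue expresses, and core genes
#' are the genes whose loading pattern aligns with the module effects.  A
#' control tissue with the same marginal structure but no core genes and no
#' trait correlation is included, as are LD-block genotypes (one block per
#' gene) for the null-GWAS correlation matrix, a gene table, auxiliary traits
#' for the shared-signal covariate, and a rare-disease gene set containing
#' the core genes.
#'
#' @param n_genes total genes (default 600).
#' @param n_core number of planted core genes (default 20).
#' @param n_factors number of co-expression factors per tissue (default 15).
#' @param n_causal number of causal tissues sharing the core-gene hub
#'   structure (default 3; phenotypes typically manifest in several
#'   tissues, and the meta-analysis is what separates consistent core
#'   genes from tissue-specific flukes).
#' @param core_loading consistent positive loading of core genes on every
#'   factor, on the scale of the background loading sd of 1 (default 1).
#' @param effect scale of the trait signal per unit of summed weighted
#'   module loading (default 0.25, which puts core-gene z-scores well clear
#'   of the N(0, 1) background while keeping the background realistic).
#' @param factor_sd_range range of the per-factor sd profile (default
#'   `c(2.5, 1.2)`); distinct variances keep eigenvectors identifiable.
#' @param n_expr_samples expression samples per tissue (default 300).
#' @param n_panel_samples genotype panel samples (default 400).
#' @param variants_per_gene LD-block size per gene window (default 4).
#' @param ld_rho within-block LD (default 0.9).
#' @param n_null null GWAS traits used for the gene-gene correlation matrix
#'   (default 200).
#' @param n_aux_traits auxiliary unrelated traits used to form the shared
#'   baseline signal (default 8, one per trait class).
#' @param noise_sd sd of the trait z-score noise (default 1).
#' @param seed integer seed.
#' @return list with components `genes` (gene_table), `panel`, `nulls`,
#'   `trait_z` (named per-gene z vector), `core_genes`, `tissues` (named list
#'   of raw expression matrices: `causal_1` ... `causal_<n_causal>` and
#'   `control`), `aux_traits`
#'   (list of per-gene z vectors with a `class` attribute each),
#'   `disease_sets` (gene_set_collection), `centromeres`.
#' @export
simulate_keygene_study <- function(n_genes = 600, n_core = 20, n_factors = 15,
                                   n_causal = 3, core_loading = 1,
                                   effect = 0.25,
                                   factor_sd_range = c(2.5, 1.2),
                                   n_expr_samples = 300,
                                   n_panel_samples = 400,
                                   variants_per_gene = 4, ld_rho = 0.9,
                                   n_null = 200, n_aux_traits = 8,
                                   noise_sd = 1, seed = 1L) {
  with_seed(seed, {
    gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
    # genes laid out on 2 chromosomes x 2 arms, one LD block per gene window
    per_chr <- ceiling(n_genes / 2)
    chrom <- rep(c("1", "2"), each = per_chr)[seq_len(n_genes)]
    idx_in_chr <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
    gene_span <- as.integer(round(stats::runif(n_genes, 10000, 60000)))
    gene_gap <- 1000000L                 # >> window, so windows never overlap
    start <- 50000L + (idx_in_chr - 1L) * (max(gene_span) + gene_gap)
    genes_df <- data.frame(gene_id = gene_ids, chromosome = chrom,
                           start = start, end = start + gene_span,
                           strand = rep(c("+", "-"), length.out = n_genes),
                           biotype = "protein_coding",
                           stringsAsFactors = FALSE)
    centromeres <- vapply(split(genes_df, genes_df$chromosome), function(d) {
      stats::median(c(d$start, d$end))   # half the genes on each arm
    }, numeric(1))
    genes <- gene_table(genes_df, centromeres)

    # genotype panel: one independent LD block centred on each gene
    blocks <- data.frame(n_variants = variants_per_gene, rho = ld_rho,
                         chromosome = genes$chromosome)
    panel <- simulate_genotypes(n_panel_samples, blocks,
                                seed = seed + 101L,
                                variant_spacing_bp = 5000L,
                                block_gap_bp = gene_gap - 100000L)
    # place each block inside its gene's window
    for (b in seq_len(n_genes)) {
      sel <- panel$variants$block == b
      width <- (sum(sel) - 1L) * 5000L
      panel$variants$position[sel] <- genes$start[b] +
        seq.int(0L, by = 5000L, length.out = sum(sel))
      panel$variants$chromosome[sel] <- genes$chromosome[b]
    }
    panel$variants$variant_id <- sprintf("v%s_%d", panel$variants$chromosome,
                                         panel$variants$position)
    colnames(panel$dosage) <- panel$variants$variant_id

    nulls <- simulate_null_gwas(panel, n_null, seed = seed + 202L)

    core <- sort(sample.int(n_genes, n_core))
    core_ids <- gene_ids[core]

    # causal tissues: factor model with *distinct* factor variances (so the
    # SVD eigenvectors track individual factors instead of arbitrary
    # rotations of them) and core genes loading positively and consistently
    # on every factor (hub behaviour).  The summed module loading drives
    # both the trait and, in these tissues, the baseline expression level:
    # trait-relevant tissues express the genes in trait loci relatively
    # highly.
    factor_sd <- seq(factor_sd_range[1], factor_sd_range[2],
                     length.out = n_factors)
    make_tissue <- function(with_core) {
      W <- matrix(stats::rnorm(n_genes * n_factors), n_genes, n_factors)
      if (with_core) W[core, ] <- core_loading + 0.1 * abs(W[core, ])
      Ws <- sweep(W, 2, factor_sd, "*")
      FF <- matrix(stats::rnorm(n_expr_samples * n_factors),
                   n_expr_samples, n_factors)
      signal <- as.numeric(Ws %*% rep(1 / sqrt(n_factors), n_factors))
      mu <- 5 + if (with_core) 0.4 * signal + stats::rnorm(n_genes, sd = 0.5)
                else stats::rnorm(n_genes, sd = 0.7)
      X <- FF %*% t(Ws) / sqrt(n_factors) +
        matrix(stats::rnorm(n_expr_samples * n_genes, sd = 1),
               n_expr_samples, n_genes)
      X <- pmax(sweep(X, 2, mu, "+"), 0)
      dimnames(X) <- list(sprintf("s%04d", seq_len(n_expr_samples)),
                          gene_ids)
      list(X = X, Ws = Ws, signal = signal)
    }
    causal <- lapply(seq_len(n_causal), function(i) make_tissue(TRUE))
    control <- make_tissue(FALSE)

    # trait gene z-scores: summed module loadings x effect + noise.  Module
    # weights are proportional to factor variance (with jitter), so the
    # large-variance modules of every causal tissue carry the association
    # and several eigenvectors per tissue come out significant.
    y_parts <- vapply(causal, function(tis) {
      b <- factor_sd^2 * (1 + 0.3 * stats::rnorm(n_factors))
      as.numeric(tis$Ws %*% b) / sqrt(n_factors)
    }, numeric(n_genes))
    trait_z <- effect * rowSums(y_parts) / sqrt(n_causal) +
      stats::rnorm(n_genes, sd = noise_sd)
    names(trait_z) <- gene_ids

    tissue_mats <- c(stats::setNames(lapply(causal, `[[`, "X"),
                                     paste0("causal_", seq_len(n_causal))),
                     list(control = control$X))

    # auxiliary unrelated traits for the shared baseline signal
    classes <- c("immune", "cancer", "skeletal", "blood composition",
                 "neuro", "cardiovascular", "metabolic", "other")
    aux <- lapply(seq_len(n_aux_traits), function(i) {
      z <- stats::rnorm(n_genes)
      names(z) <- gene_ids
      attr(z, "trait_class") <- classes[((i - 1L) %% length(classes)) + 1L]
      z
    })

    disease_sets <- gene_set_collection(
      list(core_disease = core_ids,
           unrelated_disease = gene_ids[setdiff(seq_len(n_genes), core)[1:30]]),
      genes = genes)

    list(genes = genes, panel = panel, nulls = nulls, trait_z = trait_z,
         core_genes = core_ids, tissues = tissue_mats,
         aux_traits = aux, disease_sets = disease_sets,
         centromeres = centromeres)
  })
}
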