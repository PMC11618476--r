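# A compact moduleset for unit tests: orthonormal loadings over n genes.
mk_moduleset <- function(n = 120, m = 6, seed = 1, tissue_id = "tt") {
  set.seed(seed)
  ids <- sprintf("g%03d", 1:n)
  V <- qr.Q(qr(matrix(rnorm(n * m), n, m)))
  rownames(V) <- ids
  colnames(V) <- paste0("EV", 1:m)
  structure(list(tissue_id = tissue_id, genes = ids,
                 mean_expression = setNames(runif(n, 1, 5), ids),
                 eigenvectors = V,
                 eigen_variance_fractions = rep(1 / m, m),
                 variance_threshold_used = 0.8,
                 normalisation = "vst_like"),
            class = "tissue_modules")
}

test_that("tissue selection applies Bonferroni over tissues tested", {
  ms <- mk_moduleset(n = 200, seed = 2)
  eb <- identity_basis(ms$genes)
  set.seed(3)
  # trait strongly coupled to this tissue's mean expression
  y <- 0.5 * ms$mean_expression + rnorm(200, sd = 0.5)
  names(y) <- ms$genes
  sel1 <- select_tissues(gene_zscores(y), list(tt = ms), eb)
  expect_true(sel1$significant[1])
  # with many tissues the threshold tightens: alpha / n
  many <- setNames(rep(list(ms), 5), paste0("t", 1:5))
  sel5 <- select_tissues(gene_zscores(y), many, eb)
  expect_true(all(sel5$significant == (sel5$p < 0.05 / 5)))
})

test_that("eigenvector association recovers a planted module effect", {
  ms <- mk_moduleset(n = 150, m = 5, seed = 4)
  eb <- identity_basis(ms$genes)
  set.seed(5)
  y <- 2 * ms$eigenvectors[, 3] * sqrt(150) + rnorm(150, sd = 0.3)
  names(y) <- ms$genes
  assoc <- associate_eigenvectors(gene_zscores(y), ms, eb)
  expect_true(assoc$significant[["EV3"]])
  # null trait: no module survives Bonferroni
  y0 <- setNames(rnorm(150), ms$genes)
  assoc0 <- associate_eigenvectors(gene_zscores(y0), ms, eb)
  expect_lte(assoc0$m_significant, 1)
})

test_that("the weighted sum is exact and sign-invariant", {
  V <- cbind(a = c(1, 2, 3), b = c(0, 1, 0))
  rownames(V) <- paste0("g", 1:3)
  expect_equal(v_sum(V[, "a", drop = FALSE], 2), c(g1 = 2, g2 = 4, g3 = 6))
  expect_equal(unname(v_sum(V, c(0, 0))), rep(0, 3))
  flip <- V; flip[, "a"] <- -flip[, "a"]
  expect_equal(v_sum(V, c(1.5, -2)), v_sum(flip, c(-1.5, -2)))
})

test_that("the m = 1 permutation null is the closed-form normal", {
  V <- matrix(c(0.5, -1.2, 2, 0), 4, 1,
              dimnames = list(paste0("g", 1:4), "EV1"))
  pn <- permutation_null(V, n_perm = 10000, seed = 6)
  expect_equal(unname(pn$moments[, "sd"]), unname(abs(V[, 1])),
               tolerance = 0.05)
  expect_lt(max(abs(pn$moments[1:3, "skew"])), 0.1)
  expect_true(pn$degenerate[["g4"]])
  # p = 1 for the degenerate gene, ~0.5 at the null mean
  zt <- tissue_z(setNames(c(0, 0, 0, 1), rownames(V)), pn)
  expect_equal(zt$p[zt$gene_id == "g4"], 1)
  expect_lt(abs(zt$p[zt$gene_id == "g1"] - 1), 0.05)
  expect_lt(abs(zt$z[zt$gene_id == "g1"]), 0.1)
})

test_that("fitted null p-values agree with the empirical permutation
           distribution", {
  ms <- mk_moduleset(n = 60, m = 4, seed = 7)
  V <- ms$eigenvectors
  pn <- permutation_null(V, n_perm = 10000, seed = 8, store_draws = TRUE)
  # compare fitted two-sided p with the empirical two-sided p at the
  # empirical quantiles of each gene's own null; averaging over genes
  # removes the empirical CDF's own Monte-Carlo wiggle
  probs <- c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99)
  dev <- vapply(seq_len(nrow(V)), function(i) {
    d <- pn$draws[i, ]
    qs <- quantile(d, probs)
    vapply(seq_along(qs), function(k) {
      emp <- 2 * min(mean(d <= qs[k]), mean(d >= qs[k]))
      keygene:::null_pvalue(qs[[k]], i, pn) - emp
    }, numeric(1))
  }, numeric(length(probs)))
  expect_lt(max(abs(rowMeans(dev))), 0.01)
  expect_lt(mean(abs(dev)), 0.01)
})

test_that("tissue z-scores grow with departure and carry its sign", {
  V <- matrix(c(1, 1, 1, -1, 2, 0.5), 3, 2,
              dimnames = list(paste0("g", 1:3), c("EV1", "EV2")))
  pn <- permutation_null(V, n_perm = 5000, seed = 9)
  v1 <- setNames(c(0.2, 3, -3), rownames(V))
  zt <- tissue_z(v1, pn)
  expect_gt(zt$z[2], 0)
  expect_lt(zt$z[3], 0)
  expect_gt(abs(zt$z[2]), abs(zt$z[1]))
  # two-sided p = 0.0455 corresponds to |z| ~ 2
  g1sd <- pn$moments["g1", "sd"]
  v2 <- setNames(c(2 * g1sd + pn$moments["g1", "mean"], 0, 0), rownames(V))
  zt2 <- tissue_z(v2, pn)
  expect_lt(abs(abs(zt2$z[1]) - 2), 0.15)
})

test_that("Stouffer meta-analysis matches its closed forms", {
  ids <- paste0("g", 1:3)
  Z4 <- matrix(1, 3, 4, dimnames = list(ids, paste0("t", 1:4)))
  m4 <- meta_analyse(Z4)
  expect_equal(m4$z_meta, rep(2, 3))              # 4 / sqrt(4)
  Z1 <- matrix(c(0.3, -1, 2), 3, 1, dimnames = list(ids, "t1"))
  expect_equal(meta_analyse(Z1)$z_meta, c(0.3, -1, 2))
  Z2 <- matrix(c(1, -1), 1, 2, dimnames = list("g1", c("a", "b")))
  expect_equal(meta_analyse(Z2)$z_meta, 0)
  # invariance to tissue order
  set.seed(10)
  Z <- matrix(rnorm(12), 3, 4, dimnames = list(ids, paste0("t", 1:4)))
  expect_equal(meta_analyse(Z)$z_meta,
               meta_analyse(Z[, c(3, 1, 4, 2)])$z_meta)
  # a gene missing from one tissue is combined with its own k
  Zna <- Z; Zna[1, 2] <- NA
  mna <- suppressMessages(meta_analyse(Zna))
  expect_equal(mna$k[1], 3)
  expect_equal(mna$z_meta[1], sum(Zna[1, ], na.rm = TRUE) / sqrt(3))
})

test_that("key-gene flags require both significance and annotation", {
  meta <- data.frame(gene_id = c("a", "b", "c"),
                     z_meta = c(9, 9, 1), p_meta = c(1e-12, 1e-12, 0.4),
                     k = 2, significant = c(TRUE, TRUE, FALSE))
  sets <- gene_set_collection(list(term1 = c("a", "c")), min_members = 0L)
  out <- flag_key_genes(meta, sets)
  expect_true(out$key_gene[out$gene_id == "a"])
  expect_false(out$key_gene[out$gene_id == "b"])  # significant, unannotated
  expect_false(out$key_gene[out$gene_id == "c"])  # annotated, not significant
})

test_that("tissue p-values are calibrated when effects truly come from the
           null", {
  ms <- mk_moduleset(n = 500, m = 6, seed = 11)
  V <- ms$eigenvectors
  pn <- permutation_null(V, n_perm = 10000, seed = 12)
  set.seed(13)
  hits <- replicate(40, {
    b_null <- rnorm(6)
    zt <- tissue_z(v_sum(V, b_null), pn)
    mean(zt$p < 0.05)
  })
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.07)
})

test_that("a trait with no matching tissue reports an explicit status", {
  ms <- mk_moduleset(n = 100, seed = 14)
  eb <- identity_basis(ms$genes)
  y0 <- setNames(rnorm(100), ms$genes)
  res <- suppressMessages(
    key_gene_analysis(gene_zscores(y0), list(tt = ms), eb, n_perm = 100,
                      seed = 15))
  expect_equal(res$status, "no_significant_tissue")
  expect_null(res$meta)
})
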