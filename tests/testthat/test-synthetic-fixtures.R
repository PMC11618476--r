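test_that("genotype blocks are independent at rho = 0 and reproducible", {
  panel <- simulate_genotypes(500, data.frame(n_variants = c(10, 10),
                                              rho = c(0, 0)), seed = 1)
  R <- cor(panel$dosage)
  expect_lt(mean(abs(R[upper.tri(R)])), 5 / sqrt(500))
  panel2 <- simulate_genotypes(500, data.frame(n_variants = c(10, 10),
                                               rho = c(0, 0)), seed = 1)
  expect_identical(panel$dosage, panel2$dosage)
  expect_error(simulate_genotypes(10, data.frame(n_variants = 5, rho = 0),
                                  maf_range = c(0, 0.6)), "maf_range")
})

test_that("within-block LD tracks the generative rho", {
  panel <- simulate_genotypes(2000, data.frame(n_variants = 2, rho = 0.95),
                              maf_range = c(0.2, 0.5), seed = 2)
  r <- cor(panel$dosage[, 1], panel$dosage[, 2])
  # thresholding attenuates the latent correlation a little; the empirical
  # dosage r should still be within +/- 0.1 of the latent 0.95
  expect_lt(abs(r - 0.95), 0.1)
})

test_that("null GWAS p-values are uniform and respect LD", {
  panel <- simulate_genotypes(400, data.frame(n_variants = 1000, rho = 0),
                              seed = 3)
  nulls <- simulate_null_gwas(panel, 1, seed = 4)
  expect_gt(ks.test(nulls$p[, 1], "punif")$p.value, 0.01)

  # a variant duplicated in the panel (perfect LD) gets an identical p
  panel$dosage <- cbind(panel$dosage, dup = panel$dosage[, 1])
  panel$variants <- rbind(panel$variants, panel$variants[1, ])
  panel$variants$variant_id[nrow(panel$variants)] <- "dup"
  nulls2 <- simulate_null_gwas(panel, 2, seed = 5)
  expect_equal(nulls2$p["dup", ], nulls2$p[1, ])

  nulls3 <- simulate_null_gwas(panel, 2, seed = 5)
  expect_identical(nulls2$p, nulls3$p)
})

test_that("monomorphic variants get p = 1 with a message", {
  panel <- simulate_genotypes(50, data.frame(n_variants = 3, rho = 0),
                              seed = 6)
  panel$dosage[, 2] <- 2
  expect_message(nulls <- simulate_null_gwas(panel, 1, seed = 7),
                 "monomorphic")
  expect_equal(unname(nulls$p[2, 1]), 1)
})

test_that("planted expression modules surface as leading eigenvectors", {
  # one module covering all genes, no noise: rank-1 matrix
  pe <- simulate_expression(50, 20, data.frame(size = 20, loading = 2),
                            noise_sd = 0, seed = 1)
  sv <- svd(scale(pe$matrix, scale = FALSE))
  expect_gt(sv$d[1]^2 / sum(sv$d^2), 0.999)

  # two equal orthogonal modules: each leading eigenvector loads on one
  pe2 <- simulate_expression(400, 100,
                             data.frame(size = c(30, 30), loading = c(3, 3)),
                             noise_sd = 1, seed = 2)
  sv2 <- svd(scale(pe2$matrix))
  for (j in 1:2) {
    v <- abs(sv2$v[, j])
    in1 <- mean(v[1:30]); in2 <- mean(v[31:60]); out <- mean(v[61:100])
    expect_gt(max(in1, in2) / max(out, 1e-12), 5)
  }

  # pure noise: no eigenvector dominates
  pe3 <- simulate_expression(500, 200, data.frame(size = integer(),
                                                  loading = numeric()),
                             noise_sd = 1, seed = 3)
  sv3 <- svd(scale(pe3$matrix))
  shares <- sv3$d^2 / sum(sv3$d^2)
  expect_lt(max(shares), 3 * mean(shares))
})

test_that("expression generator is deterministic and counts-like mode is
           non-negative", {
  a <- simulate_expression(20, 10, data.frame(size = 5, loading = 1),
                           seed = 9)
  b <- simulate_expression(20, 10, data.frame(size = 5, loading = 1),
                           seed = 9)
  expect_identical(a$matrix, b$matrix)
  cl <- simulate_expression(20, 10, data.frame(size = 5, loading = 1),
                            seed = 9, counts_like = TRUE)
  expect_true(all(cl$matrix >= 0))
})

test_that("omega fixture produces strong within-block gene correlation", {
  fx <- simulate_omega_fixture(n_blocks = 10, genes_per_block = 4,
                               n_samples = 300, n_null = 200, seed = 1)
  M <- as_matrix(fx$omega)
  same_block <- outer(sub("_.*", "", rownames(M)), sub("_.*", "", colnames(M)),
                      "==") & upper.tri(M)
  diff_block <- !outer(sub("_.*", "", rownames(M)), sub("_.*", "", colnames(M)),
                       "==") & upper.tri(M)
  expect_gt(mean(M[same_block]), 0.5)
  expect_lt(mean(abs(M[diff_block])), 0.15)
})
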