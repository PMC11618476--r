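test_that("inverse normal transform follows the rank formula", {
  got <- inverse_normal_transform(c(10, 20, 30))
  expect_equal(got, qnorm(c(1, 3, 5) / 6))
  # invariant to monotone transforms
  set.seed(1)
  x <- rnorm(40)
  expect_equal(inverse_normal_transform(x), inverse_normal_transform(exp(x)))
  expect_equal(inverse_normal_transform(rep(7, 5)), rep(0, 5))
})

test_that("rotation behaves as a projection", {
  ids <- paste0("g", 1:10)
  eb <- identity_basis(ids)                      # vectors = identity
  y <- setNames(rnorm(10), ids)
  fit_env <- keygene:::rotate_design(y, NULL, eb, ids)
  # identity basis: rotation permutes at most; norms preserved
  expect_equal(sort(abs(fit_env$y_rot)), sort(abs(unname(y))))
  # truncated basis: contraction
  eb2 <- truncate_eigen(random_corr(10, seed = 2), 0.7)
  y2 <- setNames(rnorm(10), eb2$genes)
  rot <- keygene:::rotate_design(y2, NULL, eb2, eb2$genes)
  expect_lte(sqrt(sum(rot$y_rot^2)), sqrt(sum(y2^2)) + 1e-12)
  # a response orthogonal to every retained eigenvector rotates to zero
  v_perp <- qr.Q(qr(eb2$vectors), complete = TRUE)[, ncol(eb2$vectors) + 1]
  names(v_perp) <- eb2$genes
  rot0 <- keygene:::rotate_design(v_perp, NULL, eb2, eb2$genes)
  expect_lt(max(abs(rot0$y_rot)), 1e-10)
})

test_that("with identity correlation the fit equals OLS exactly", {
  set.seed(3)
  ids <- paste0("g", 1:50)
  eb <- identity_basis(ids)
  y <- setNames(rnorm(50), ids)
  x <- setNames(rnorm(50), ids)
  cv <- cbind(c1 = setNames(rnorm(50), ids))
  fit <- gls_eigen(y, x, eb, covariates = cv, transform_y = FALSE)
  ref <- summary(lm(y ~ x + cv))$coefficients
  expect_lt(abs(coef(fit)[["x"]] - ref["x", 1]), 1e-10)
  expect_lt(abs(fit$se[["x"]] - ref["x", 2]), 1e-10)
  expect_equal(fit$df, 50 - 3)
  expect_equal(unname(fit$t[["x"]] * fit$se[["x"]]), unname(coef(fit)[["x"]]),
               tolerance = 1e-12)
})

test_that("full retention reproduces exact GLS from the explicit inverse", {
  M <- random_corr(20, seed = 4, prefix = "h")
  ids <- rownames(M)
  eb <- truncate_eigen(M, 1.0)
  set.seed(5)
  y <- setNames(rnorm(20), ids)
  x <- setNames(rnorm(20), ids)
  fit <- gls_eigen(y, x, eb, transform_y = FALSE)
  oracle <- gls_exact(y, x, solve(M))
  expect_lt(abs(coef(fit)[["x"]] - oracle$beta[["x"]]), 1e-8)
  expect_lt(abs(fit$se[["x"]] - oracle$se[["x"]]), 1e-8)
})

test_that("regressing a vector on itself gives beta exactly 1", {
  M <- random_corr(15, seed = 6)
  eb <- truncate_eigen(M, 1.0)
  x <- setNames(rnorm(15), eb$genes)
  fit <- gls_eigen(x, x, eb, transform_y = FALSE)
  expect_equal(unname(coef(fit)[["x"]]), 1, tolerance = 1e-10)
})

test_that("scale equivariance and covariate orthogonality", {
  M <- random_corr(30, seed = 7)
  eb <- truncate_eigen(M, 0.9)
  set.seed(8)
  y <- setNames(rnorm(30), eb$genes)
  x <- setNames(rnorm(30), eb$genes)
  f1 <- gls_eigen(y, x, eb, transform_y = FALSE)
  f2 <- gls_eigen(y, 5 * x, eb, transform_y = FALSE)
  expect_equal(unname(coef(f2)[["x"]]), unname(coef(f1)[["x"]]) / 5,
               tolerance = 1e-10)
  expect_equal(unname(f2$t[["x"]]), unname(f1$t[["x"]]), tolerance = 1e-10)
  expect_equal(unname(f2$p[["x"]]), unname(f1$p[["x"]]), tolerance = 1e-10)

  # a covariate orthogonal to x after rotation leaves beta_x unchanged
  keep <- eb$values > 1e-10
  V <- eb$vectors[, keep, drop = FALSE]
  Li <- 1 / eb$values[keep]
  xr <- drop(crossprod(V, x))
  ones_r <- drop(crossprod(V, rep(1, 30)))
  A <- cbind(xr, ones_r)
  # build a covariate orthogonal (in the weighted inner product) to both x'
  # and the rotated intercept, by a joint weighted projection
  set.seed(9)
  cr <- rnorm(length(xr))
  AtLiA <- crossprod(A, A * Li)
  cr <- cr - drop(A %*% solve(AtLiA, crossprod(A, cr * Li)))
  cv <- drop(V %*% cr)   # back to gene space (V orthonormal columns)
  names(cv) <- eb$genes
  f3 <- gls_eigen(y, x, eb, covariates = cbind(c1 = cv), transform_y = FALSE)
  expect_equal(unname(coef(f3)[["x"]]), unname(coef(f1)[["x"]]),
               tolerance = 1e-8)
})

test_that("collinear designs fail with an informative error", {
  ids <- paste0("g", 1:20)
  eb <- identity_basis(ids)
  y <- setNames(rnorm(20), ids)
  x <- setNames(rnorm(20), ids)
  cv <- cbind(dup = 2 * x)
  rownames(cv) <- ids
  expect_error(gls_eigen(y, x, eb, covariates = cv, transform_y = FALSE),
               "collinear")
})

test_that("the calibration experiment is well calibrated for GLS and
           inflated for OLS", {
  fx <- simulate_omega_fixture(n_blocks = 30, genes_per_block = 6,
                               n_samples = 400, n_null = 300, seed = 10)
  cal <- calibration_experiment(fx$omega, n_genes = 150, n_pathways = 400,
                                seed = 11)
  expect_gt(cal$type1[["ols"]], 0.10)
  expect_gt(cal$type1[["approx_gls"]], 0.02)
  expect_lt(cal$type1[["approx_gls"]], 0.08)
  # approximate-GLS p-values are uniform under the null
  expect_gt(ks.test(cal$p_values[, "approx_gls"], "punif")$p.value, 0.01)
})
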