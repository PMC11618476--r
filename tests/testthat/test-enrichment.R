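test_that("Fisher enrichment reproduces its closed-form examples", {
  # balanced table: no association
  uni <- paste0("g", 1:40)
  sel <- uni[1:20]; term <- uni[c(1:10, 21:30)]
  r <- fisher_enrichment(sel, term, uni)
  expect_equal(r$a, 10); expect_equal(r$b, 10)
  expect_equal(r$c, 10); expect_equal(r$d, 10)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p, 1)

  # (20, 80; 10, 190): OR = 20*190 / (80*10)
  uni2 <- paste0("h", 1:300)
  sel2 <- uni2[1:100]                # a + b = 100
  term2 <- uni2[c(1:20, 101:110)]    # a = 20, c = 10
  r2 <- fisher_enrichment(sel2, term2, uni2)
  expect_equal(c(r2$a, r2$b, r2$c, r2$d), c(20, 80, 10, 190))
  expect_equal(r2$odds_ratio, 4.75)
  expect_equal(r2$p, fisher_oracle_p(20, 80, 10, 190), tolerance = 1e-9)

  # complete overlap boundary: infinite OR convention
  r3 <- fisher_enrichment(uni[1:12], uni[1:12], uni)
  expect_equal(r3$odds_ratio, Inf)
  expect_lt(r3$p, 1e-6)
})

test_that("Fisher p equals the hypergeometric oracle across enumerated and
           random tables", {
  # exhaustive over all tables with total n <= 20
  for (n in c(8, 13, 20)) {
    combos <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    combos <- combos[rowSums(combos) <= n, ]
    combos$d <- n - rowSums(combos)
    for (i in seq_len(nrow(combos))) {
      a <- combos$a[i]; b <- combos$b[i]; cc <- combos$c[i]; d <- combos$d[i]
      p_impl <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
      expect_equal(p_impl, fisher_oracle_p(a, b, cc, d), tolerance = 1e-7,
                   info = paste(a, b, cc, d))
    }
  }
  # randomised tables up to n = 60
  set.seed(1)
  for (i in 1:200) {
    n <- sample(21:60, 1)
    cuts <- sort(sample(0:n, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]; cc <- cuts[3] - cuts[2]
    d <- n - cuts[3]
    p_impl <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    expect_equal(p_impl, fisher_oracle_p(a, b, cc, d), tolerance = 1e-7,
                 info = paste(a, b, cc, d))
  }
})

test_that("the enrichment driver skips small terms and adjusts p-values", {
  uni <- paste0("g", 1:100)
  sets <- gene_set_collection(list(big = uni[1:30], small = uni[1:5]),
                              min_members = 0L)
  out <- enrichment_test(uni[1:25], sets, uni)
  expect_true(out$skipped[out$term_id == "small"])
  expect_false(out$skipped[out$term_id == "big"])
  expect_equal(out$p_adjusted, pmin(1, out$p * 1))   # one tested term
  # t-test variant needs scores and runs
  sc <- setNames(rnorm(100), uni)
  out_t <- enrichment_test(uni[1:25], sets, uni, method = "ttest",
                           scores = sc)
  expect_false(is.na(out_t$p[out_t$term_id == "big"]))
})

test_that("AUC equals brute-force pair counting with midrank ties", {
  sc <- setNames(c(5, 4, 1, 3, 2), paste0("g", 1:5))
  # members g1 g2 g3 vs non-members g4 g5: U = 4 wins of 6 pairs
  expect_equal(auc_enrichment(sc, paste0("g", 1:3)), 4 / 6)
  expect_equal(auc_enrichment(sc, c("g1", "g2")), 1)  # strictly above

  set.seed(2)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    scores <- setNames(sample(1:8, n, replace = TRUE), paste0("x", 1:n))
    members <- paste0("x", sample(n, sample(n - 1, 1)))
    mem <- names(scores) %in% members
    pairs <- outer(scores[mem], scores[!mem],
                   function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc_enrichment(scores, members), mean(pairs))
    # negating scores flips the AUC
    expect_equal(auc_enrichment(-scores, members),
                 1 - auc_enrichment(scores, members))
  }

  # independent scores: AUC near 1/2
  big <- setNames(rnorm(4000), paste0("b", 1:4000))
  expect_lt(abs(auc_enrichment(big, paste0("b", 1:2000)) - 0.5), 0.05)
})

test_that("greedy clumping matches a brute-force oracle on a printed toy", {
  v <- data.frame(
    variant_id = paste0("v", 1:6), chromosome = "1",
    position = c(100e3, 150e3, 220e3, 900e3, 950e3, 2e6),
    p_value = c(1e-10, 1e-9, 0.2, 5e-9, 1e-12, 1e-8))
  class(v) <- c("variant_table", "data.frame")
  r <- matrix(0, 6, 6, dimnames = list(v$variant_id, v$variant_id))
  diag(r) <- 1
  r["v1", "v2"] <- r["v2", "v1"] <- 0.8
  r["v1", "v3"] <- r["v3", "v1"] <- 0.5
  r["v4", "v5"] <- r["v5", "v4"] <- 0.9
  cs <- clump(v, r, p_threshold = 5e-8, r2_threshold = 0.1,
              window_bp = 500000)
  # oracle by hand: v5 (1e-12) absorbs v4; v1 (1e-10) absorbs v2 and v3
  # (r2 = 0.25 >= 0.1, within window); v6 is its own clump (p = 1e-8 < 5e-8)
  expect_setequal(cs$index$variant_id, c("v5", "v1", "v6"))
  expect_equal(unname(cs$membership[c("v2", "v3")]), c("v1", "v1"))
  expect_equal(unname(cs$membership[["v4"]]), "v5")
  expect_true(is.na(cs$membership[["v3"]]) == FALSE)

  # no variant below threshold: zero clumps
  v0 <- v; v0$p_value <- 0.5
  expect_equal(nrow(clump(v0, r)$index), 0L)

  # single significant isolated variant: singleton clump
  v1 <- v[6, ]
  cs1 <- clump(v1, r)
  expect_equal(cs1$index$variant_id, "v6")
  expect_equal(cs1$index$n_members, 1L)

  # invariance to input row order
  perm <- v[sample(6), ]
  cs2 <- clump(perm, r)
  expect_setequal(cs2$index$variant_id, cs$index$variant_id)
  expect_equal(cs2$membership[names(cs$membership)], cs$membership)
})

test_that("distance diagnostics handle TSS hits and chromosome gaps", {
  gt <- tiny_genes()
  clumps <- structure(list(index = data.frame(
    variant_id = "v1", chromosome = "1", position = gt["g1", "tss"],
    p_value = 1e-10, n_members = 1L)), class = "clump_set")
  sc <- setNames(rnorm(6), gt$gene_id)
  d <- distance_to_key_genes(clumps, gt, sc)
  expect_equal(d$distances$distance[d$distances$gene_id == "g1"], 0)
  # chromosome 2 genes are excluded entirely
  expect_false(any(grepl("^g[456]$", d$distances$gene_id)))

  # planted trans-only architecture: all signals far from every gene
  far <- structure(list(index = data.frame(
    variant_id = "w", chromosome = "1", position = 5e7,
    p_value = 1e-10, n_members = 1L)), class = "clump_set")
  d2 <- distance_to_key_genes(far, gt, sc)
  expect_equal(d2$fraction_far, 1)
})
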