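# Post-hoc statistics: gene-set enrichment of prioritised genes (Fisher
# exact and Mann-Whitney AUC, plus a t-test variant), greedy clumping of
# GWAS variants, and clump-to-gene distance diagnostics.

#' Fisher enrichment of a selected gene set in annotation terms
#'
#' For each term, the 2x2 table of membership (selected vs not, in term vs
#' not) over the analysis universe is tested with a two-sided Fisher exact
#' test.  The odds ratio is reported as `(a*d)/(b*c)` (infinite when the
#' off-diagonal product is zero) and p-values are Bonferroni-corrected over
#' the terms actually tested.  Terms with fewer than `min_members` universe
#' genes are skipped and recorded.  A t-test variant
#' (`method = "ttest"`) comparing a per-gene score between term members and
#' non-members is also available; Fisher is the default (the two appear in
#' different descriptions of the same analysis in the field; both are kept,
#' with the discrepancy surfaced here rather than resolved silently).
#'
#' @param selected character vector of prioritised gene ids (subset of
#'   `universe`).
#' @param sets a [gene_set_collection()].
#' @param universe character vector of all analysed gene ids.
#' @param method `"fisher"` (default) or `"ttest"`.
#' @param scores named per-gene scores; required for `method = "ttest"`.
#' @param min_members minimum term size after intersection (default 10).
#' @return data.frame per tested term: `term_id`, `a`, `b`, `c`, `d`
#'   (2x2 counts), `odds_ratio`, `auc`, `p`, `p_adjusted`, `skipped`.
#' @export
enrichment_test <- function(selected, sets, universe,
                            method = c("fisher", "ttest"), scores = NULL,
                            min_members = 10L) {
  method <- match.arg(method)
  check_that(all(selected %in% universe), "selected must be within universe")
  if (method == "ttest")
    check_that(!is.null(scores), "scores required for the t-test variant")
  rows <- lapply(names(sets$members), function(tid) {
    term <- intersect(sets$members[[tid]], universe)
    if (length(term) < min_members)
      return(data.frame(term_id = tid, a = NA, b = NA, c = NA, d = NA,
                        odds_ratio = NA, auc = NA, p = NA,
                        skipped = TRUE, stringsAsFactors = FALSE))
    a <- length(intersect(selected, term))
    b <- length(selected) - a
    cc <- length(term) - a
    d <- length(universe) - a - b - cc
    or <- if (b * cc > 0) (a * d) / (b * cc) else Inf
    p <- if (method == "fisher") {
      stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    } else {
      member <- universe %in% term
      stats::t.test(scores[universe][member],
                    scores[universe][!member])$p.value
    }
    auc <- if (!is.null(scores))
      auc_enrichment(scores[universe], term) else NA_real_
    data.frame(term_id = tid, a = a, b = b, c = cc, d = d, odds_ratio = or,
               auc = auc, p = p, skipped = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_tested <- sum(!out$skipped)
  out$p_adjusted <- pmin(1, out$p * n_tested)
  rownames(out) <- NULL
  out
}

#' Fisher enrichment of one selected set in one term
#'
#' Single-term convenience wrapper around [enrichment_test()].
#'
#' @param selected,term,universe character vectors of gene ids.
#' @return one-row data.frame (see [enrichment_test()]).
#' @export
fisher_enrichment <- function(selected, term, universe) {
  sets <- gene_set_collection(list(term = term), min_members = 0L)
  enrichment_test(selected, sets, universe, min_members = 0L)
}

#' Mann-Whitney AUC of scores against set membership
#'
#' The Mann-Whitney U statistic of member vs non-member scores divided by
#' the product of the group sizes: the probability that a random member
#' outscores a random non-member, with ties counted half (midranks).
#'
#' @param scores named per-gene scores.
#' @param term character vector of member gene ids.
#' @return AUC in `[0, 1]`.
#' @export
auc_enrichment <- function(scores, term) {
  member <- names(scores) %in% term
  n1 <- sum(member); n2 <- sum(!member)
  check_that(n1 >= 1 && n2 >= 1, "need at least one member and one non-member")
  r <- rank(scores)                      # midranks for ties
  U <- sum(r[member]) - n1 * (n1 + 1) / 2
  U / (n1 * n2)
}

#' Greedy LD clumping of GWAS variants
#'
#' Repeatedly takes the unassigned variant with the smallest p-value below
#' `p_threshold` (ties broken by position) as an index variant and absorbs
#' every unassigned variant on the same chromosome within `window_bp` whose
#' squared correlation with the index reaches `r2_threshold`.
#'
#' @param variants a `variant_table` with p-values.
#' @param ld variant x variant correlation matrix with variant ids as
#'   dimnames (e.g. `cor(panel$dosage)`); pairs absent from it are treated
#'   as uncorrelated.
#' @param p_threshold index significance threshold (default 5e-8).
#' @param r2_threshold membership threshold on r-squared (default 0.1).
#' @param window_bp clump half-width (default 500000).
#' @return a `clump_set`: list with `index` (data.frame of index variants:
#'   `variant_id`, `chromosome`, `position`, `p_value`, `n_members`) and
#'   `membership` (named vector: variant id -> index id, NA if unassigned).
#' @export
clump <- function(variants, ld, p_threshold = 5e-8, r2_threshold = 0.1,
                  window_bp = 500000) {
  v <- as.data.frame(variants)
  v <- v[order(v$p_value, v$position), ]
  assigned <- stats::setNames(rep(NA_character_, nrow(v)), v$variant_id)
  index_rows <- list()
  for (i in seq_len(nrow(v))) {
    id <- v$variant_id[i]
    if (!is.na(assigned[id]) || v$p_value[i] >= p_threshold) next
    cand <- v$variant_id[is.na(assigned[v$variant_id]) &
                         v$chromosome == v$chromosome[i] &
                         abs(v$position - v$position[i]) <= window_bp]
    r <- rep(0, length(cand))
    known <- cand %in% rownames(ld) & id %in% colnames(ld)
    if (any(known)) r[known] <- ld[cand[known], id]
    members <- cand[r^2 >= r2_threshold | cand == id]
    assigned[members] <- id
    index_rows[[id]] <- data.frame(variant_id = id,
                                   chromosome = v$chromosome[i],
                                   position = v$position[i],
                                   p_value = v$p_value[i],
                                   n_members = length(members),
                                   stringsAsFactors = FALSE)
  }
  index <- if (length(index_rows)) do.call(rbind, index_rows)
           else data.frame(variant_id = character(), chromosome = character(),
                           position = integer(), p_value = numeric(),
                           n_members = integer())
  rownames(index) <- NULL
  structure(list(index = index,
                 membership = assigned[variants$variant_id]),
            class = "clump_set")
}

#' @export
print.clump_set <- function(x, ...) {
  cat("Clump set:", nrow(x$index), "clump(s),",
      sum(!is.na(x$membership)), "of", length(x$membership),
      "variants assigned\n")
  invisible(x)
}

#' Distance from key genes to the nearest independent GWAS signal
#'
#' For every gene, the distance from its TSS to the nearest clump index
#' variant on the same chromosome; genes on chromosomes without any clump
#' are excluded.  Reports the Pearson correlation between distance and the
#' key gene score and the fraction of gene-signal pairs farther than
#' `far_bp` — the diagnostic for a trans-acting architecture.
#'
#' @param clumps a [clump()] result.
#' @param genes a [gene_table()].
#' @param scores named per-gene key gene scores (e.g. meta z).
#' @param far_bp distance considered "far" (default 500000).
#' @return list with `distances` (data.frame `gene_id`, `distance`,
#'   `score`), `correlation`, `fraction_far`.
#' @export
distance_to_key_genes <- function(clumps, genes, scores, far_bp = 500000) {
  check_that(nrow(clumps$index) >= 1, "no clumps available")
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    idx <- clumps$index[clumps$index$chromosome == genes$chromosome[i], ,
                        drop = FALSE]
    if (nrow(idx) == 0L) return(NULL)
    data.frame(gene_id = genes$gene_id[i],
               distance = min(abs(idx$position - genes$tss[i])),
               stringsAsFactors = FALSE)
  })
  dist <- do.call(rbind, rows)
  check_that(!is.null(dist), "no gene shares a chromosome with a clump")
  dist$score <- scores[dist$gene_id]
  ok <- !is.na(dist$score)
  corr <- if (sum(ok) > 2 && stats::sd(dist$distance[ok]) > 0 &&
              stats::sd(dist$score[ok]) > 0)
    stats::cor(dist$distance[ok], dist$score[ok]) else NA_real_
  list(distances = dist, correlation = corr,
       fraction_far = mean(dist$distance > far_bp))
}
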