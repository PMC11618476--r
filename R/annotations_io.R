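# Readers/writers for the external formats and the coordinate conventions
# shared by every stage.  All coordinates are 1-based and inclusive; the only
# place an offset ever appears is an explicit converter.

#' Build a validated gene annotation table
#'
#' The gene table is the coordinate backbone of the whole analysis: windows
#' around genes, clump-to-gene distances and gene density are all computed
#' from it.  The transcription start site (TSS) is the strand-aware outermost
#' position of the gene (start on `+`, end on `-`), and each gene is assigned
#' to a chromosome arm so that the gene-gene correlation matrix can be built
#' per arm.
#'
#' @param df data.frame with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`) and `biotype`.
#' @param centromeres named numeric vector mapping chromosome name to the
#'   centromere position (bp).
#' @param protein_coding_only keep only genes with biotype
#'   `"protein_coding"` (default `TRUE`, matching how gene-level scores are
#'   computed for protein-coding genes).
#' @return a `gene_table`: data.frame with the input columns plus `tss` and
#'   `arm`, one row per gene, unique `gene_id`.
#' @examples
#' gt <- gene_table(
#'   data.frame(gene_id = "g1", chromosome = "1", start = 100L, end = 200L,
#'              strand = "+", biotype = "protein_coding"),
#'   centromeres = c("1" = 5000))
#' gt$tss  # 100: plus strand, outermost position is the start
#' @export
gene_table <- function(df, centromeres, protein_coding_only = TRUE) {
  need <- c("gene_id", "chromosome", "start", "end", "strand", "biotype")
  miss <- setdiff(need, names(df))
  check_that(length(miss) == 0L,
             paste("gene table is missing columns:", paste(miss, collapse = ", ")))
  df <- as.data.frame(df)[need]
  df$chromosome <- as.character(df$chromosome)
  df$gene_id <- as.character(df$gene_id)
  if (protein_coding_only) df <- df[df$biotype == "protein_coding", , drop = FALSE]
  check_that(nrow(df) > 0L, "gene table is empty after filtering")
  check_that(!anyDuplicated(df$gene_id), "duplicated gene_id in gene table")
  check_that(all(df$start <= df$end), "gene with start > end")
  check_that(all(df$strand %in% c("+", "-")), "strand must be '+' or '-'")
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df$arm <- assign_arm(df$chromosome, df$start, df$end, centromeres)
  rownames(df) <- df$gene_id
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Assign genes to chromosome arms
#'
#' A gene lies on the p arm if it ends before the centromere and on the q arm
#' if it starts after it.  A gene spanning the centromere is assigned by the
#' position of its midpoint, with a midpoint exactly at the centromere going
#' to q.  Any fixed rule preserves the block structure of the gene-gene
#' correlation matrix; this one is deterministic and documented.
#'
#' @param chromosome,start,end vectors describing each gene.
#' @param centromeres named numeric vector, chromosome -> centromere bp.
#' @return character vector, `"p"` or `"q"` per gene.
#' @export
assign_arm <- function(chromosome, start, end, centromeres) {
  chromosome <- as.character(chromosome)
  missing_chr <- setdiff(unique(chromosome), names(centromeres))
  check_that(length(missing_chr) == 0L,
             paste("no centromere position for chromosome(s):",
                   paste(missing_chr, collapse = ", ")))
  cen <- unname(centromeres[chromosome])
  mid <- (start + end) / 2
  ifelse(end < cen, "p", ifelse(start > cen, "q", ifelse(mid < cen, "p", "q")))
}

#' Read gene annotations from a TSV file
#'
#' @param path TSV with header columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`, `biotype`.
#' @inheritParams gene_table
#' @return a [gene_table()].
#' @export
read_gene_annotations <- function(path, centromeres, protein_coding_only = TRUE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c(gene_id = "character",
                                         chromosome = "character"),
                          stringsAsFactors = FALSE)
  gene_table(df, centromeres, protein_coding_only = protein_coding_only)
}

#' Write a gene table back to TSV
#' @param genes a [gene_table()].
#' @param path output file.
#' @export
write_gene_annotations <- function(genes, path) {
  utils::write.table(
    as.data.frame(genes)[c("gene_id", "chromosome", "start", "end",
                           "strand", "biotype")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS variant-level summary statistics
#'
#' Reads a tab-separated summary-statistics file into a variant table.
#' Rows with a missing variant id are dropped; any id occurring more than
#' once is removed entirely (all copies), because an ambiguous id cannot be
#' matched to the LD reference.  Rows with p-values outside `[0, 1]` are
#' rejected (counted in the `"n_rejected"` attribute); p-values below the
#' floor are raised to it so that the later z-conversion stays finite while
#' preserving ordering.  Variants at minor allele frequency at or below
#' `maf_threshold` are removed when a MAF column is present.
#'
#' @param path TSV file with a header.
#' @param maf_threshold variants kept require `maf > maf_threshold`
#'   (default 0.05).
#' @param p_floor lower clamp applied to p-values (default `1e-300`).
#' @param columns named character vector mapping the roles
#'   `id`, `chrom`, `pos`, `p` (and optionally `maf`) to column names in the
#'   file; defaults to the common `SNP`, `CHR`, `BP`, `P`, `MAF`.
#' @return a `variant_table`: data.frame with columns `variant_id`,
#'   `chromosome`, `position`, `p_value` (and `maf` if available), attribute
#'   `n_rejected` counting malformed rows.
#' @export
read_summary_stats <- function(path, maf_threshold = 0.05, p_floor = .P_FLOOR,
                               columns = c(id = "SNP", chrom = "CHR",
                                           bp = "BP", p = "P", maf = "MAF")) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  for (role in c("id", "chrom", "bp", "p"))
    check_that(columns[[role]] %in% names(raw),
               paste0("column '", columns[[role]], "' (", role,
                      ") not found in ", path))
  df <- data.frame(variant_id = as.character(raw[[columns[["id"]]]]),
                   chromosome = as.character(raw[[columns[["chrom"]]]]),
                   position   = as.integer(raw[[columns[["bp"]]]]),
                   p_value    = as.numeric(raw[[columns[["p"]]]]),
                   stringsAsFactors = FALSE)
  has_maf <- "maf" %in% names(columns) && columns[["maf"]] %in% names(raw)
  if (has_maf) df$maf <- as.numeric(raw[[columns[["maf"]]]])

  # drop rows without an id, then all copies of any duplicated id
  df <- df[!is.na(df$variant_id) & nzchar(df$variant_id), , drop = FALSE]
  dup <- df$variant_id %in% df$variant_id[duplicated(df$variant_id)]
  df <- df[!dup, , drop = FALSE]

  bad_p <- is.na(df$p_value) | df$p_value < 0 | df$p_value > 1
  n_rejected <- sum(bad_p)
  if (n_rejected > 0L)
    message(n_rejected, " row(s) with malformed p-values rejected")
  df <- df[!bad_p, , drop = FALSE]
  df$p_value <- floor_p(df$p_value, p_floor)

  if (has_maf) df <- df[!is.na(df$maf) & df$maf > maf_threshold, , drop = FALSE]
  check_that(nrow(df) > 0L, "no variants left after filtering")
  rownames(df) <- NULL
  attr(df, "n_rejected") <- n_rejected
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Write variant summary statistics to TSV
#'
#' Writes in the default column dialect of [read_summary_stats()] so that a
#' write/read round trip is lossless.
#'
#' @param variants a `variant_table`.
#' @param path output file.
#' @export
write_summary_stats <- function(variants, path) {
  out <- data.frame(SNP = variants$variant_id, CHR = variants$chromosome,
                    BP = variants$position, P = variants$p_value)
  if (!is.null(variants$maf)) out$MAF <- variants$maf
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one term per line, tab-separated
#' `term_id<TAB>description<TAB>member1<TAB>member2...`.  Members are
#' intersected with the analysis gene universe; terms left with fewer than
#' `min_members` genes are flagged as excluded rather than deleted, so the
#' caller can still inspect them.
#'
#' @param path GMT file.
#' @param genes optional gene universe (a [gene_table()] or character vector
#'   of gene ids); members outside it are dropped.
#' @param min_members terms with fewer surviving members are flagged
#'   `excluded` (default 10).
#' @return a `gene_set_collection`: list with `terms` (data.frame of
#'   `term_id`, `term_name`, `n_members`, `excluded`) and `members` (named
#'   list of character vectors).
#' @export
read_gmt <- function(path, genes = NULL, min_members = 10L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list(), character(), min_members = min_members))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  check_that(!anyDuplicated(ids),
             paste("duplicate term_id in GMT:",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  names_ <- vapply(parts, function(x) if (length(x) >= 2) x[2] else "", character(1))
  members <- lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  names(members) <- ids
  gene_set_collection(members, names_, genes = genes, min_members = min_members)
}

#' Construct a gene-set collection
#'
#' @param members named list of character vectors (term_id -> member ids).
#' @param term_names optional character vector of display names.
#' @inheritParams read_gmt
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(members, term_names = names(members),
                                genes = NULL, min_members = 10L) {
  if (inherits(genes, "gene_table")) genes <- genes$gene_id
  if (!is.null(genes)) {
    n_before <- vapply(members, length, integer(1))
    members <- lapply(members, intersect, genes)
    n_dropped <- n_before - vapply(members, length, integer(1))
    if (length(n_dropped) && sum(n_dropped) > 0L)
      message(sum(n_dropped), " gene-set member(s) absent from the gene ",
              "universe dropped")
  }
  n <- vapply(members, length, integer(1))
  terms <- data.frame(
    term_id = if (length(members)) names(members) else character(),
    term_name = if (length(members)) as.character(term_names) else character(),
    n_members = as.integer(n),
    excluded = n < min_members,
    stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  structure(list(terms = terms, members = members,
                 min_members = as.integer(min_members)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", nrow(x$terms), "term(s),",
      sum(!x$terms$excluded), "usable (>=", x$min_members, "members)\n")
  invisible(x)
}

#' Convert between 1-based inclusive and 0-based half-open intervals
#'
#' The package uses 1-based inclusive coordinates everywhere; these two
#' converters are the only place an offset appears.
#'
#' @param start,end interval in 1-based inclusive coordinates.
#' @return data.frame with the converted `start`/`end`.
#' @export
to_half_open <- function(start, end) data.frame(start = start - 1L, end = end)

#' @rdname to_half_open
#' @export
from_half_open <- function(start, end) data.frame(start = start + 1L, end = end)
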