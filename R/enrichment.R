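#' Gene set container
#'
#' @param ids Character vector of gene IDs (deduplicated, nonempty).
#' @param name Set name.
#' @param namespace `"mouse"` or `"human"`.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(ids, name = "set", namespace = c("mouse", "human")) {
  namespace <- match.arg(namespace)
  ids <- unique(as.character(ids))
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stop("gene set '", name, "' is empty")
  structure(list(name = name, ids = ids, namespace = namespace),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%s): %d genes\n", x$name, x$namespace,
              length(x$ids)))
  invisible(x)
}

#' Translate mouse gene IDs to human homologs
#'
#' Genes with an entry in the mapping table are translated; unmapped genes
#' are dropped (count logged); many-to-one collisions are deduplicated.
#'
#' @param genes A [gene_set()] (mouse namespace).
#' @param table Data frame with columns `mouse_id`, `human_id`.
#' @return A [gene_set()] in the human namespace.
#' @export
map_homologs <- function(genes, table) {
  stopifnot(inherits(genes, "gene_set"))
  if (is.null(table) || nrow(table) == 0L) stop("empty homolog mapping table")
  stopifnot(all(c("mouse_id", "human_id") %in% names(table)))
  hit <- match(genes$ids, table$mouse_id)
  dropped <- sum(is.na(hit))
  if (dropped > 0) msg("map_homologs: %d of %d genes unmapped, dropped",
                       dropped, length(genes$ids))
  mapped <- table$human_id[hit[!is.na(hit)]]
  gene_set(unique(mapped), genes$name, "human")
}

#' Hypergeometric odds-ratio enrichment of a query set in a gene list
#'
#' One-sided upper-tail hypergeometric test of the overlap between a query
#' gene set and a gene list within a background universe:
#' `p = P[X >= a]` with `X ~ Hypergeom(N = |background|,
#' K = |list in background|, n = |query|)`. The odds ratio is `(a d)/(b c)`
#' from the 2x2 table; if any cell is zero the Haldane-Anscombe +0.5
#' correction is applied to all four cells (switchable).
#'
#' @param query A [gene_set()], subset of the background.
#' @param list A [gene_set()]; intersected with the background before testing.
#' @param background A [gene_set()]: the post-filter gene universe.
#' @param haldane Apply the +0.5 zero-cell correction to the OR (default
#'   `TRUE`).
#' @return One-row data frame: `list_name`, `overlap` (a), `query_only` (b),
#'   `list_only` (c), `neither` (d), `odds_ratio`, `p`, and the overlap IDs
#'   in `attr(, "overlap_ids")`.
#' @export
hypergeom_enrich <- function(query, list, background, haldane = TRUE) {
  stopifnot(inherits(query, "gene_set"), inherits(list, "gene_set"),
            inherits(background, "gene_set"))
  bad <- setdiff(query$ids, background$ids)
  if (length(bad))
    stop("query genes not in background: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5) else "")
  N <- length(background$ids)
  lst <- intersect(list$ids, background$ids)
  K <- length(lst)
  n <- length(query$ids)
  a <- length(intersect(query$ids, lst))
  b <- n - a
  cc <- K - a
  d <- N - K - b
  p <- stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
  cells <- c(a, b, cc, d)
  if (haldane && any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  out <- data.frame(list_name = list$name, overlap = a, query_only = b,
                    list_only = cc, neither = d, odds_ratio = or, p = p)
  attr(out, "overlap_ids") <- intersect(query$ids, lst)
  out
}

#' Enrichment of query classes against a gene-list collection
#'
#' Runs [hypergeom_enrich()] for every (query, list) pair and corrects the
#' p values by Benjamini-Hochberg across the whole invocation — the FDR
#' family is all tests run together.
#'
#' @param queries Named list of [gene_set()]s (e.g. the M+F- and M-F+
#'   classes).
#' @param lists Named list of [gene_set()]s (e.g. read from a GMT file).
#' @param background The universe [gene_set()].
#' @param haldane Passed to [hypergeom_enrich()].
#' @return Data frame with one row per (query, list) pair, columns of
#'   [hypergeom_enrich()] plus `query_name` and `q`.
#' @export
enrich_classes <- function(queries, lists, background, haldane = TRUE) {
  rows <- list()
  for (qn in names(queries)) for (ln in names(lists)) {
    r <- hypergeom_enrich(queries[[qn]], lists[[ln]], background, haldane)
    r$query_name <- qn
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[, c("query_name", "list_name", "overlap", "query_only", "list_only",
          "neither", "odds_ratio", "p", "q")]
}

#' Per-chromosome disproportionality of a DE class
#'
#' For each chromosome, tests whether the class genes are enriched among
#' that chromosome's background genes (hypergeometric upper tail), reports
#' the percentage of the chromosome's genes falling in the class, and BH-
#' corrects across chromosomes. Chromosomes with no background genes are
#' skipped with a warning.
#'
#' @param class_genes A [gene_set()] of class members (subset of background).
#' @param gene_chroms Data frame with columns `gene_id`, `chrom` covering
#'   every background gene.
#' @param background The universe [gene_set()].
#' @param haldane Passed to [hypergeom_enrich()].
#' @return Data frame: `chrom`, `n_chrom`, `overlap`, `percent`,
#'   `odds_ratio`, `p`, `q`.
#' @export
chromosome_enrich <- function(class_genes, gene_chroms, background,
                              haldane = TRUE) {
  stopifnot(inherits(class_genes, "gene_set"), inherits(background, "gene_set"))
  missing_chrom <- setdiff(background$ids, gene_chroms$gene_id)
  if (length(missing_chrom))
    stop("background genes without chromosome label: ",
         paste(utils::head(missing_chrom, 5), collapse = ", "))
  gc <- gene_chroms[gene_chroms$gene_id %in% background$ids, ]
  rows <- list()
  for (ch in sort(unique(gc$chrom))) {
    ids <- gc$gene_id[gc$chrom == ch]
    if (!length(ids)) { warning("chromosome ", ch, " has no background genes"); next }
    r <- hypergeom_enrich(class_genes, gene_set(ids, ch, background$namespace),
                          background, haldane)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, n_chrom = length(ids), overlap = r$overlap,
      percent = 100 * r$overlap / length(ids),
      odds_ratio = r$odds_ratio, p = r$p)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Benjamini-Hochberg false-discovery-rate q values
#'
#' Step-up BH adjustment (order-preserving, monotone), via
#' `stats::p.adjust`.
#'
#' @param pvals Numeric p values in `[0, 1]`.
#' @return q values of the same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
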