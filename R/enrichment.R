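# Hypergeometric over-representation of annotation terms in a gene set,
# with BH FDR — the enrichment statistic used for GO/KEGG-style term tables.

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= k) for X ~ Hypergeometric(N, K, n): the
#' chance of drawing at least \code{k} term-annotated genes when sampling
#' \code{n} genes without replacement from a universe of \code{N} genes of
#' which \code{K} carry the term.
#'
#' @param k observed term genes in the set.
#' @param K term genes in the universe.
#' @param n set size.
#' @param N universe size.
#' @return Upper-tail p-value (vectorized over the four arguments).
#' @export
hypergeom_test <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 1 | k > n | k > K | n > N | K > N
  if (any(bad))
    stop("inconsistent counts: need 0 <= k <= min(K, n), n <= N, K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation in a gene set
#'
#' Tests every annotation term represented in the gene set against the
#' annotation universe with \code{\link{hypergeom_test}}, then adjusts
#' across the tested terms with Benjamini-Hochberg.
#'
#' @param gene_set character vector of gene ids (e.g. a DEG list).
#' @param annotation data frame with columns \code{gene_id}, \code{term_id}
#'   and optionally \code{term_name}; one row per gene-term link.
#' @param universe gene universe; defaults to all annotated genes.
#' @param alpha FDR threshold for the \code{significant} flag (default
#'   0.05).
#' @return Data frame sorted by \code{fdr} then \code{p} with one row per
#'   term having at least one set gene: \code{term_id}, \code{term_name},
#'   \code{k}, \code{K}, \code{n}, \code{N}, \code{p}, \code{fdr},
#'   \code{significant}.
#' @export
enrich <- function(gene_set, annotation, universe = NULL, alpha = 0.05) {
  for (col in c("gene_id", "term_id"))
    if (is.null(annotation[[col]])) stop("annotation is missing column ", col)
  if (is.null(universe))
    universe <- unique(annotation$gene_id)
  universe <- unique(as.character(universe))
  if (!length(universe))
    stop("empty gene universe")
  gene_set <- unique(as.character(gene_set))
  outside <- setdiff(gene_set, universe)
  if (length(outside)) {
    warning(length(outside), " gene(s) in the set are outside the universe",
            " and were dropped")
    gene_set <- intersect(gene_set, universe)
  }
  anno <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  anno <- anno[!duplicated(anno[c("gene_id", "term_id")]), , drop = FALSE]
  N <- length(universe)
  n <- length(gene_set)
  K_all <- table(anno$term_id)
  in_set <- anno[anno$gene_id %in% gene_set, , drop = FALSE]
  if (!nrow(in_set)) {
    out <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), fdr = numeric(),
                      significant = logical())
    return(out)
  }
  k_tab <- table(in_set$term_id)
  terms <- names(k_tab)
  k <- as.integer(k_tab)
  K <- as.integer(K_all[terms])
  term_name <- if (!is.null(anno$term_name))
    anno$term_name[match(terms, anno$term_id)] else terms
  p <- hypergeom_test(k, K, n, N)
  fdr <- bh_adjust(p)
  out <- data.frame(term_id = terms, term_name = term_name,
                    k = k, K = K, n = n, N = N, p = p, fdr = fdr,
                    significant = fdr <= alpha, row.names = NULL)
  out[order(out$fdr, out$p, out$term_id), , drop = FALSE]
}
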