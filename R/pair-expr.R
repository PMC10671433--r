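# Assemble the six expression contexts of each homoeolog pair from the
# three species matrices.

#' Pair-level expression contexts
#'
#' For every homoeolog pair, collects the four replicate vectors that all
#' pair-level analyses use: the A^r gene in the diploid parent (A^rp), the
#' partner homoeolog in the tetraploid parent (O^p, O = A^n or C^n), and the
#' same two genes in the hybrid (A^rh, O^h). The hybrid pair total
#' (A^rh + O^h per replicate) is derived downstream.
#'
#' @param pairs data frame with \code{ar_gene}, \code{partner_gene},
#'   \code{partner_subgenome} (see \code{\link{reciprocal_best_hits}}).
#' @param parent1 \code{\link{expression_matrix}} of the A^r parent (FPKM).
#' @param parent2 \code{\link{expression_matrix}} of the A^n/C^n parent.
#' @param hybrid \code{\link{expression_matrix}} of the hybrid.
#' @return Object of class \code{"pair_expr"}: list with \code{pairs} (the
#'   pair table, with \code{pair_id}) and replicate matrices \code{ar_p},
#'   \code{o_p}, \code{ar_h}, \code{o_h} (pairs x replicates).
#' @export
pair_expression <- function(pairs, parent1, parent2, hybrid) {
  stopifnot(inherits(parent1, "expression_matrix"),
            inherits(parent2, "expression_matrix"),
            inherits(hybrid, "expression_matrix"))
  for (col in c("ar_gene", "partner_gene", "partner_subgenome"))
    if (is.null(pairs[[col]])) stop("pairs is missing column ", col)
  miss <- setdiff(pairs$ar_gene, rownames(parent1$values))
  if (length(miss))
    stop("A^r gene(s) absent from parent1: ", miss[1],
         if (length(miss) > 1) sprintf(" (+%d more)", length(miss) - 1))
  miss <- setdiff(pairs$partner_gene, rownames(parent2$values))
  if (length(miss))
    stop("partner gene(s) absent from parent2: ", miss[1],
         if (length(miss) > 1) sprintf(" (+%d more)", length(miss) - 1))
  miss <- setdiff(c(pairs$ar_gene, pairs$partner_gene),
                  rownames(hybrid$values))
  if (length(miss))
    stop("gene(s) absent from hybrid: ", miss[1],
         if (length(miss) > 1) sprintf(" (+%d more)", length(miss) - 1))
  pairs <- as.data.frame(pairs)
  if (is.null(pairs$pair_id))
    pairs$pair_id <- paste(pairs$ar_gene, pairs$partner_gene, sep = "|")
  structure(
    list(pairs = pairs,
         ar_p = parent1$values[pairs$ar_gene, , drop = FALSE],
         o_p = parent2$values[pairs$partner_gene, , drop = FALSE],
         ar_h = hybrid$values[pairs$ar_gene, , drop = FALSE],
         o_h = hybrid$values[pairs$partner_gene, , drop = FALSE]),
    class = "pair_expr")
}

#' @export
print.pair_expr <- function(x, ...) {
  cat(sprintf("pair_expr: %d homoeolog pairs, %d replicates\n",
              nrow(x$pairs), ncol(x$ar_p)))
  invisible(x)
}

#' Expressed-pair filter
#'
#' Keeps the pairs expressed in at least one parent: mean FPKM >=
#' \code{floor} in the A^rp or the O^p context. Pairs silent in both parents
#' carry no information for bias or dominance analysis.
#'
#' @param pe a \code{\link{pair_expression}} object.
#' @param floor FPKM floor (default 1, the conventional low-expression
#'   boundary).
#' @return Filtered \code{"pair_expr"} object.
#' @export
filter_expressed <- function(pe, floor = 1) {
  stopifnot(inherits(pe, "pair_expr"), floor >= 0)
  keep <- rowMeans(pe$ar_p) >= floor | rowMeans(pe$o_p) >= floor
  pe$pairs <- pe$pairs[keep, , drop = FALSE]
  for (m in c("ar_p", "o_p", "ar_h", "o_h"))
    pe[[m]] <- pe[[m]][keep, , drop = FALSE]
  rownames(pe$pairs) <- NULL
  pe
}
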