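# Differential expression between two species contexts: log2 fold change
# with pseudocount, Student t-test on log2(FPKM+1), BH correction, and
# threshold-based up/down/ns calls.

#' Log2 fold change with pseudocount
#'
#' \code{log2((mean_a + pc) / (mean_b + pc))}; the pseudocount keeps
#' zero-expression genes finite and symmetric.
#'
#' @param mean_a,mean_b non-negative mean abundances (vectorized).
#' @param pseudocount positive stabilizer added to both means (default 1).
#' @return Numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  if (any(mean_a < 0, na.rm = TRUE) || any(mean_b < 0, na.rm = TRUE))
    stop("means must be non-negative")
  log2((mean_a + pseudocount) / (mean_b + pseudocount))
}

#' Two-sample Student t-test on log-transformed abundances
#'
#' Two-sided equal-variance t-test on \code{log2(x + 1)} transformed
#' replicate values, the test used throughout the pipeline (DEG calls and
#' the pair-level HEB/ELD battery). Groups with zero pooled variance give
#' p = 1 when the means agree and p = 0 otherwise.
#'
#' @param reps_a,reps_b numeric vectors of replicate abundances (>= 2 each).
#' @param log apply the \code{log2(x + 1)} transform first (default TRUE;
#'   set FALSE if the values are already on a log scale).
#' @return Two-sided p-value.
#' @export
two_sample_test <- function(reps_a, reps_b, log = TRUE) {
  if (length(reps_a) < 2L || length(reps_b) < 2L)
    stop("at least 2 replicates per group are required")
  if (log) {
    reps_a <- log2p1(reps_a)
    reps_b <- log2p1(reps_b)
  }
  row_student_t(matrix(reps_a, 1L), matrix(reps_b, 1L))$p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input order is preserved and
#' adjusted values are capped at 1.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Threshold DEG call
#'
#' \code{"up"} when log2FC >= \code{lfc} and adjusted p < \code{alpha};
#' \code{"down"} when log2FC <= -\code{lfc} and adjusted p < \code{alpha};
#' otherwise \code{"ns"}. The fold-change boundary is inclusive.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param padj adjusted p-values.
#' @param lfc absolute log2 fold-change threshold (default 2).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return Character vector in \code{c("up", "down", "ns")}.
#' @export
classify_deg <- function(log2fc, padj, lfc = 2, alpha = 0.05) {
  stopifnot(lfc > 0, alpha > 0, alpha < 1)
  out <- rep("ns", length(log2fc))
  out[log2fc >= lfc & padj < alpha] <- "up"
  out[log2fc <= -lfc & padj < alpha] <- "down"
  out
}

#' Per-gene differential expression table
#'
#' Runs the fold-change / t-test / BH / threshold battery on the genes
#' shared by two expression matrices (matched by gene id). "up" means
#' higher in \code{em_a}.
#'
#' @param em_a,em_b \code{\link{expression_matrix}} objects in FPKM.
#' @param pseudocount pseudocount for the fold change.
#' @param lfc,alpha DEG thresholds (see \code{\link{classify_deg}}).
#' @return Data frame with \code{gene_id}, \code{mean_a}, \code{mean_b},
#'   \code{log2fc}, \code{p}, \code{padj}, \code{call}.
#' @export
deg_table <- function(em_a, em_b, pseudocount = 1, lfc = 2, alpha = 0.05) {
  stopifnot(inherits(em_a, "expression_matrix"),
            inherits(em_b, "expression_matrix"))
  shared <- intersect(em_a$genes$gene_id, em_b$genes$gene_id)
  if (!length(shared))
    stop("the two matrices share no gene ids")
  a <- em_a$values[shared, , drop = FALSE]
  b <- em_b$values[shared, , drop = FALSE]
  tt <- row_student_t(log2p1(a), log2p1(b))
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  lfc_v <- log2_fold_change(mean_a, mean_b, pseudocount)
  padj <- bh_adjust(tt$p)
  data.frame(gene_id = shared, mean_a = mean_a, mean_b = mean_b,
             log2fc = lfc_v, p = tt$p, padj = padj,
             call = classify_deg(lfc_v, padj, lfc, alpha),
             row.names = NULL)
}
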