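# Homoeolog expression bias (HEB): which member of a homoeolog pair is the
# stronger expresser, tested separately within the hybrid and between the
# parents, then cross-classified.

HEB_STATES <- c("Ar_biased", "partner_biased", "unbiased")
HEB_CATEGORIES <- c("conserved_bias", "novel_bias", "reversed_bias",
                    "lost_bias", "unbiased")

#' Bias state of one homoeolog pair
#'
#' Student t-test (on log2(FPKM+1)) between the A^r-side and partner-side
#' replicate vectors: \code{"Ar_biased"} when p < alpha and the A^r mean is
#' larger, \code{"partner_biased"} when p < alpha and smaller, otherwise
#' \code{"unbiased"}.
#'
#' @param vec_ar,vec_other replicate FPKM vectors (>= 2 each).
#' @param alpha significance level (default 0.05).
#' @return One of \code{"Ar_biased"}, \code{"partner_biased"},
#'   \code{"unbiased"}.
#' @export
bias_state <- function(vec_ar, vec_other, alpha = 0.05) {
  if (length(vec_ar) < 2L || length(vec_other) < 2L)
    stop("at least 2 replicates per group are required")
  tt <- row_student_t(matrix(log2p1(vec_ar), 1L),
                      matrix(log2p1(vec_other), 1L))
  c(greater = "Ar_biased", less = "partner_biased",
    ns = "unbiased")[[test_outcome(tt, alpha)]]
}

# vectorized bias state over pair matrices
bias_state_rows <- function(mat_ar, mat_other, alpha) {
  tt <- row_student_t(log2p1(mat_ar), log2p1(mat_other))
  list(state = unname(c(greater = "Ar_biased", less = "partner_biased",
                        ns = "unbiased")[test_outcome(tt, alpha)]),
       p = tt$p)
}

#' Cross-classify hybrid vs parental bias
#'
#' Deterministic mapping of the two bias states:
#' \itemize{
#'   \item equal non-unbiased states -> \code{"conserved_bias"} (the hybrid
#'     holds the parental condition);
#'   \item both unbiased -> \code{"unbiased"};
#'   \item parental unbiased, hybrid biased -> \code{"novel_bias"};
#'   \item opposite biases -> \code{"reversed_bias"};
#'   \item parental biased, hybrid unbiased -> \code{"lost_bias"}.
#' }
#'
#' @param hybrid_state,parental_state bias states (vectorized).
#' @return Character vector of categories.
#' @export
classify_heb <- function(hybrid_state, parental_state) {
  stopifnot(all(hybrid_state %in% HEB_STATES),
            all(parental_state %in% HEB_STATES),
            length(hybrid_state) == length(parental_state))
  h_un <- hybrid_state == "unbiased"
  p_un <- parental_state == "unbiased"
  out <- character(length(hybrid_state))
  out[h_un & p_un] <- "unbiased"
  out[!h_un & p_un] <- "novel_bias"
  out[h_un & !p_un] <- "lost_bias"
  same <- !h_un & !p_un & hybrid_state == parental_state
  out[same] <- "conserved_bias"
  out[!h_un & !p_un & !same] <- "reversed_bias"
  out
}

#' HEB calls for all pairs
#'
#' @param pe a \code{\link{pair_expression}} object (usually after
#'   \code{\link{filter_expressed}}).
#' @param alpha significance level for both t-tests (default 0.05).
#' @return Data frame with one row per pair: \code{pair_id},
#'   \code{partner_subgenome}, \code{hybrid_state}, \code{parental_state},
#'   \code{category}, \code{p_hybrid}, \code{p_parental}.
#' @export
heb_calls <- function(pe, alpha = 0.05) {
  stopifnot(inherits(pe, "pair_expr"), alpha >= 0, alpha <= 1)
  hyb <- bias_state_rows(pe$ar_h, pe$o_h, alpha)
  par <- bias_state_rows(pe$ar_p, pe$o_p, alpha)
  data.frame(pair_id = pe$pairs$pair_id,
             partner_subgenome = pe$pairs$partner_subgenome,
             hybrid_state = hyb$state, parental_state = par$state,
             category = classify_heb(hyb$state, par$state),
             p_hybrid = hyb$p, p_parental = par$p,
             row.names = NULL)
}

#' Summarize HEB calls
#'
#' Counts and within-stratum proportions per partner subgenome, crossed by
#' hybrid bias state and category. Proportions sum to 1 within each
#' partner-subgenome stratum.
#'
#' @param calls output of \code{\link{heb_calls}}.
#' @return Data frame with \code{partner_subgenome}, \code{hybrid_state},
#'   \code{category}, \code{n}, \code{prop}.
#' @export
heb_summary <- function(calls) {
  if (is.null(calls) || !nrow(calls))
    stop("empty HEB call table")
  agg <- stats::aggregate(list(n = rep(1L, nrow(calls))),
                          by = calls[c("partner_subgenome", "hybrid_state",
                                       "category")],
                          FUN = sum)
  tot <- tapply(agg$n, agg$partner_subgenome, sum)
  agg$prop <- agg$n / as.numeric(tot[agg$partner_subgenome])
  agg <- agg[order(agg$partner_subgenome, -agg$n), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
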