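# Expression-level dominance (ELD), additivity and transgressive
# classification of homoeolog pairs, plus the per-homoeolog mechanism
# linkage (which homoeolog moved to produce the dominance pattern).

ELD_CATEGORIES <- c("no_change", "additivity",
                    "ELD_P1_high", "ELD_P1_low",
                    "ELD_P2_high", "ELD_P2_low",
                    "transgressive_up", "transgressive_down",
                    "ambiguous")
CHANGE_STATES <- c("up", "unchanged", "down")

#' ELD category levels
#'
#' The classifier's output vocabulary. \code{concrete_only = TRUE} drops
#' \code{"ambiguous"}, leaving the eight realizable truth categories used by
#' the simulator: parental equivalence (\code{no_change}), additivity, four
#' dominance categories (total matching parent 1 or parent 2, each at the
#' high or low parental level), and transgressive up/down.
#'
#' @param concrete_only drop the \code{"ambiguous"} label.
#' @return Character vector of category names.
#' @export
eld_categories <- function(concrete_only = FALSE) {
  if (concrete_only) setdiff(ELD_CATEGORIES, "ambiguous") else ELD_CATEGORIES
}

#' Pair-level test triple
#'
#' The three Student t-tests (on log2(FPKM+1)) that drive the ELD decision
#' table for one pair: parent 1 context vs parent 2 context (A^rp vs O^p),
#' hybrid pair total vs parent 1, and hybrid pair total vs parent 2. The
#' hybrid total is A^rh + O^h computed per replicate on the FPKM scale, so
#' replicate variance is preserved for the test.
#'
#' @param ar_p,o_p,ar_h,o_h replicate FPKM vectors of the four contexts.
#' @param alpha significance level (default 0.05).
#' @return List with \code{outcome} (named character vector
#'   \code{t_parents}, \code{t_h1}, \code{t_h2}, values in
#'   \code{c("greater", "less", "ns")}) and \code{p} (the three p-values).
#' @export
pair_tests <- function(ar_p, o_p, ar_h, o_h, alpha = 0.05) {
  tt <- eld_tests_rows(matrix(ar_p, 1L), matrix(o_p, 1L),
                       matrix(ar_h, 1L), matrix(o_h, 1L), alpha)
  list(outcome = c(t_parents = tt$t_parents, t_h1 = tt$t_h1,
                   t_h2 = tt$t_h2),
       p = c(t_parents = tt$p_parents, t_h1 = tt$p_h1, t_h2 = tt$p_h2))
}

# vectorized test triple over pair matrices
eld_tests_rows <- function(ar_p, o_p, ar_h, o_h, alpha) {
  total_h <- log2p1(ar_h + o_h)
  p1 <- log2p1(ar_p)
  p2 <- log2p1(o_p)
  t_par <- row_student_t(p1, p2)
  t_h1 <- row_student_t(total_h, p1)
  t_h2 <- row_student_t(total_h, p2)
  list(t_parents = test_outcome(t_par, alpha),
       t_h1 = test_outcome(t_h1, alpha),
       t_h2 = test_outcome(t_h2, alpha),
       p_parents = t_par$p, p_h1 = t_h1$p, p_h2 = t_h2$p)
}

#' ELD decision table
#'
#' Maps the 27 possible test-outcome triples to a category:
#' \itemize{
#'   \item all three \code{ns} -> \code{no_change} (hybrid equivalent to
#'     both parents, parents equivalent to each other);
#'   \item total differs from both parents in the same direction ->
#'     \code{transgressive_up} / \code{transgressive_down};
#'   \item total indistinguishable from parent 1 but different from parent 2
#'     in the same direction as parent 1 itself, parents differing ->
#'     \code{ELD_P1_high} (parent 1 the higher parent) or
#'     \code{ELD_P1_low}; mirrored for \code{ELD_P2};
#'   \item total strictly between two differing parents (significantly below
#'     the high parent and above the low one) -> \code{additivity};
#'   \item every remaining (direction-conflicting or underdetermined)
#'     combination -> \code{ambiguous}.
#' }
#'
#' @param t_parents,t_h1,t_h2 outcomes in \code{c("greater", "less", "ns")}:
#'   parent1 vs parent2, hybrid total vs parent1, hybrid total vs parent2
#'   (vectorized). Alternatively pass a \code{\link{pair_tests}} result as
#'   \code{t_parents}.
#' @return Character vector of categories.
#' @export
classify_eld <- function(t_parents, t_h1, t_h2) {
  if (is.list(t_parents) && !is.null(t_parents$outcome)) {
    o <- t_parents$outcome
    t_h2 <- o[["t_h2"]]; t_h1 <- o[["t_h1"]]; t_parents <- o[["t_parents"]]
  }
  ok <- c("greater", "less", "ns")
  stopifnot(all(t_parents %in% ok), all(t_h1 %in% ok), all(t_h2 %in% ok))
  n <- length(t_parents)
  stopifnot(length(t_h1) == n, length(t_h2) == n)
  out <- rep("ambiguous", n)
  out[t_parents == "ns" & t_h1 == "ns" & t_h2 == "ns"] <- "no_change"
  out[t_h1 == "greater" & t_h2 == "greater"] <- "transgressive_up"
  out[t_h1 == "less" & t_h2 == "less"] <- "transgressive_down"
  par_sig <- t_parents != "ns"
  # total == parent1, total vs parent2 agrees with parent1 vs parent2
  p1_dom <- t_h1 == "ns" & par_sig & t_h2 == t_parents
  out[p1_dom & t_parents == "greater"] <- "ELD_P1_high"
  out[p1_dom & t_parents == "less"] <- "ELD_P1_low"
  # total == parent2, total vs parent1 agrees with parent2 vs parent1
  p2_dom <- t_h2 == "ns" & par_sig & t_h1 == flip_outcome(t_parents)
  out[p2_dom & t_parents == "less"] <- "ELD_P2_high"
  out[p2_dom & t_parents == "greater"] <- "ELD_P2_low"
  # strictly between two differing parents
  additive <- par_sig & t_h1 == flip_outcome(t_parents) & t_h2 == t_parents
  out[additive] <- "additivity"
  out
}

#' ELD calls for all pairs
#'
#' @param pe a \code{\link{pair_expression}} object.
#' @param alpha significance level for the three t-tests (default 0.05).
#' @return Data frame with \code{pair_id}, \code{partner_subgenome},
#'   \code{category}, the three outcomes and the three p-values.
#' @export
eld_calls <- function(pe, alpha = 0.05) {
  stopifnot(inherits(pe, "pair_expr"), alpha >= 0, alpha <= 1)
  tt <- eld_tests_rows(pe$ar_p, pe$o_p, pe$ar_h, pe$o_h, alpha)
  data.frame(pair_id = pe$pairs$pair_id,
             partner_subgenome = pe$pairs$partner_subgenome,
             category = classify_eld(tt$t_parents, tt$t_h1, tt$t_h2),
             t_parents = tt$t_parents, t_h1 = tt$t_h1, t_h2 = tt$t_h2,
             p_parents = tt$p_parents, p_h1 = tt$p_h1, p_h2 = tt$p_h2,
             row.names = NULL)
}

#' Homoeolog-level mechanism linkage
#'
#' For each pair, tests each homoeolog's hybrid expression against its own
#' parental context (A^rh vs A^rp, O^h vs O^p) and records the 3x3 case of
#' (A^r change, partner change), each in \code{up}/\code{unchanged}/
#' \code{down}. Stratifying these cases by ELD category shows which
#' homoeolog's movement produced the dominance pattern.
#'
#' @param pe a \code{\link{pair_expression}} object.
#' @param alpha significance level (default 0.05).
#' @return Data frame with \code{pair_id}, \code{partner_subgenome},
#'   \code{ar_change}, \code{partner_change}, \code{case_id} (the ordered
#'   pair, e.g. \code{"unchanged:up"}), \code{p_ar}, \code{p_partner}.
#' @export
linkage_calls <- function(pe, alpha = 0.05) {
  stopifnot(inherits(pe, "pair_expr"), alpha >= 0, alpha <= 1)
  map <- c(greater = "up", ns = "unchanged", less = "down")
  t_ar <- row_student_t(log2p1(pe$ar_h), log2p1(pe$ar_p))
  t_o <- row_student_t(log2p1(pe$o_h), log2p1(pe$o_p))
  ar_change <- unname(map[test_outcome(t_ar, alpha)])
  partner_change <- unname(map[test_outcome(t_o, alpha)])
  data.frame(pair_id = pe$pairs$pair_id,
             partner_subgenome = pe$pairs$partner_subgenome,
             ar_change = ar_change, partner_change = partner_change,
             case_id = paste(ar_change, partner_change, sep = ":"),
             p_ar = t_ar$p, p_partner = t_o$p,
             row.names = NULL)
}

#' Summarize ELD and linkage calls
#'
#' Category counts and proportions per partner subgenome, and (when linkage
#' calls are supplied) a 3x3 (A^r change x partner change) contingency table
#' per ELD category.
#'
#' @param calls output of \code{\link{eld_calls}}.
#' @param linkage optional output of \code{\link{linkage_calls}} on the same
#'   pairs.
#' @return List with \code{category} (data frame
#'   \code{partner_subgenome, category, n, prop}; proportions sum to 1 per
#'   subgenome) and \code{linkage} (named list of 3x3 tables, or NULL).
#' @export
eld_summary <- function(calls, linkage = NULL) {
  if (is.null(calls) || !nrow(calls))
    stop("empty ELD call table")
  agg <- stats::aggregate(list(n = rep(1L, nrow(calls))),
                          by = calls[c("partner_subgenome", "category")],
                          FUN = sum)
  tot <- tapply(agg$n, agg$partner_subgenome, sum)
  agg$prop <- agg$n / as.numeric(tot[agg$partner_subgenome])
  agg <- agg[order(agg$partner_subgenome, -agg$n), , drop = FALSE]
  rownames(agg) <- NULL
  link_tabs <- NULL
  if (!is.null(linkage)) {
    if (!all(calls$pair_id %in% linkage$pair_id))
      stop("linkage calls are missing pairs present in the ELD calls")
    lk <- linkage[match(calls$pair_id, linkage$pair_id), , drop = FALSE]
    link_tabs <- lapply(split(lk, calls$category), function(d)
      table(factor(d$ar_change, CHANGE_STATES),
            factor(d$partner_change, CHANGE_STATES),
            dnn = c("ar_change", "partner_change")))
  }
  list(category = agg, linkage = link_tabs)
}
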