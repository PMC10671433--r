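# Shared fixtures and independent oracles.

# small expression matrix with controllable values
make_em <- function(values, species = "AA", unit = "fpkm",
                    subgenome = NULL, length_bp = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  ids <- if (is.null(rownames(values))) sprintf("g%03d", seq_len(n))
         else rownames(values)
  expression_matrix(values, ids,
                    subgenome %||% rep("Ar", n),
                    length_bp %||% rep(1000, n),
                    species = species, unit = unit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pair_expr object built directly from four replicate matrices
make_pe <- function(ar_p, o_p, ar_h, o_h, partner_subgenome = "An") {
  n <- nrow(as.matrix(ar_p))
  pairs <- data.frame(ar_gene = sprintf("ArG%03d", seq_len(n)),
                      partner_gene = sprintf("AnG%03d", seq_len(n)),
                      partner_subgenome = rep(partner_subgenome,
                                              length.out = n))
  pairs$pair_id <- paste(pairs$ar_gene, pairs$partner_gene, sep = "|")
  structure(list(pairs = pairs, ar_p = as.matrix(ar_p),
                 o_p = as.matrix(o_p), ar_h = as.matrix(ar_h),
                 o_h = as.matrix(o_h)),
            class = "pair_expr")
}

# replicate matrix around a log2 mean
reps_around <- function(mean_log2, n_rows, n_reps, sd = 0.5) {
  2^(mean_log2 + matrix(rnorm(n_rows * n_reps, 0, sd), n_rows, n_reps))
}

# Independent brute-force evaluator of the dominance taxonomy, written from
# the category semantics (hybrid total H vs parental levels P1, P2) rather
# than the package's rule order.
oracle_eld <- function(tp, t1, t2) {
  if (tp == "ns" && t1 == "ns" && t2 == "ns") return("no_change")
  if (t1 != "ns" && t1 == t2)
    return(if (t1 == "greater") "transgressive_up" else "transgressive_down")
  if (tp != "ns") {
    p1_high <- tp == "greater"
    # H == P1 and H differs from P2 on P1's side
    if (t1 == "ns" && ((p1_high && t2 == "greater") ||
                       (!p1_high && t2 == "less")))
      return(if (p1_high) "ELD_P1_high" else "ELD_P1_low")
    # H == P2 and H differs from P1 on P2's side
    if (t2 == "ns" && ((p1_high && t1 == "less") ||
                       (!p1_high && t1 == "greater")))
      return(if (p1_high) "ELD_P2_low" else "ELD_P2_high")
    # H strictly between differing parents
    if ((p1_high && t1 == "less" && t2 == "greater") ||
        (!p1_high && t1 == "greater" && t2 == "less"))
      return("additivity")
  }
  "ambiguous"
}

# naive O(m^2) step-up BH oracle
oracle_bh <- function(p) {
  m <- length(p)
  r <- vapply(p, function(x) sum(p <= x), 0L) # max rank within ties
  q <- pmin(1, m * p / r)
  vapply(seq_len(m),
         function(i) min(q[p >= p[i]]),
         0)
}

# brute-force reciprocal best hits on a bit-score matrix
# (rows = forward queries, cols = reverse queries)
oracle_rbh <- function(score) {
  out <- NULL
  for (i in seq_len(nrow(score))) {
    j <- which.max(score[i, ])
    if (which.max(score[, j]) == i)
      out <- rbind(out, data.frame(ar_gene = rownames(score)[i],
                                   partner_gene = colnames(score)[j]))
  }
  out[order(out$ar_gene), , drop = FALSE]
}

# BLAST-style hit tables in both directions from a score matrix
hits_from_scores <- function(score) {
  qs <- rep(rownames(score), ncol(score))
  ss <- rep(colnames(score), each = nrow(score))
  fwd <- data.frame(query_id = qs, subject_id = ss,
                    e_value = 10^(-as.vector(score)),
                    bit_score = as.vector(score))
  rev <- data.frame(query_id = ss, subject_id = qs,
                    e_value = fwd$e_value, bit_score = fwd$bit_score)
  list(fwd = fwd, rev = rev)
}
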