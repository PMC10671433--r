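# Internal statistical helpers shared across modules.

#' @keywords internal
log2p1 <- function(x) log2(x + 1)

#' @keywords internal
log10p1 <- function(x) log10(x + 1)

# Vectorized equal-variance (Student) two-sample t-test over matrix rows.
# Degenerate rows (zero pooled variance) get p = 1 when the group means are
# equal and p = 0 otherwise; stats::t.test refuses such input outright.
#' @keywords internal
row_student_t <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  na <- ncol(a)
  nb <- ncol(b)
  if (na < 2L || nb < 2L)
    stop("at least 2 replicates per group are required")
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- sp2 <= 0
  if (any(degenerate)) {
    eq <- ma[degenerate] == mb[degenerate]
    p[degenerate] <- ifelse(eq, 1, 0)
    tstat[degenerate] <- ifelse(eq, 0, sign(ma - mb)[degenerate] * Inf)
  }
  list(statistic = tstat, df = df, p = p, mean_a = ma, mean_b = mb)
}

# Three-valued test outcome used by the HEB/ELD classifiers: "greater" /
# "less" when p < alpha (direction from the group means), else "ns".
#' @keywords internal
test_outcome <- function(tt, alpha) {
  out <- rep("ns", length(tt$p))
  sig <- tt$p < alpha
  out[sig & tt$mean_a > tt$mean_b] <- "greater"
  out[sig & tt$mean_a < tt$mean_b] <- "less"
  out
}

#' @keywords internal
flip_outcome <- function(x) {
  ifelse(x == "greater", "less", ifelse(x == "less", "greater", "ns"))
}
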