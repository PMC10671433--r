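# Seeded generator of parental and hybrid replicate FPKM matrices with known
# per-pair HEB/ELD/linkage truth states. Replicate values are log-normal:
# 2^(mean_log2 + N(0, noise_sd_log2)).

#' Simulation configuration
#'
#' Study-design parameters of the synthetic allopolyploid experiment. The
#' defaults emulate a 3-replicate bulk RNA-seq design with log-normal
#' replicate noise of 0.5 on the log2 scale, pair baselines centred at
#' log2 FPKM 5 with spread 1, and an 8-fold (3 log2 units) shift for every
#' simulated parental or hybrid effect.
#'
#' @param n_pairs number of homoeolog pairs to simulate.
#' @param n_reps replicates per species (>= 2, default 3).
#' @param category_mix named vector of proportions over the concrete ELD
#'   truth categories (\code{eld_categories(concrete_only = TRUE)});
#'   entries must be non-negative and sum to 1. Default: uniform over the
#'   eight categories.
#' @param effect_log2 magnitude (log2 units) of parent-vs-parent and hybrid
#'   shifts (default 3).
#' @param noise_sd_log2 replicate noise SD in log2 space (> 0, default 0.5).
#' @param base_expr_log2 mean of the per-pair baseline log2 expression
#'   (default 5).
#' @param base_sd_log2 SD of the per-pair baseline (default 1; 0 gives a
#'   flat baseline).
#' @param hybrid_bias_log2 log2 ratio of the A^r homoeolog to the partner
#'   homoeolog within the hybrid pair total (default 0: even split). Use a
#'   non-zero value to realize hybrid-biased (HEB) pairs while keeping the
#'   pair total, and hence the ELD category, fixed.
#' @param eld_mechanism how ELD categories are realized at the homoeolog
#'   level: \code{"balanced"} splits the pair total per
#'   \code{hybrid_bias_log2} and keeps the total exactly at the dominant
#'   parent's level; \code{"partner"} keeps A^r exactly at its parental
#'   level and shifts the partner homoeolog by \code{effect_log2} toward
#'   the dominant parent (exact per-homoeolog changes, approximate total;
#'   applies to ELD_P1 categories).
#' @param dosage_scale halve the hybrid means of the partner (A^n/C^n)
#'   homoeologs to mimic one-copy dosage in the triploid (default FALSE).
#' @param seed integer RNG seed.
#' @return Object of class \code{"sim_config"} (a validated list).
#' @export
sim_config <- function(n_pairs, n_reps = 3L, category_mix = NULL,
                       effect_log2 = 3, noise_sd_log2 = 0.5,
                       base_expr_log2 = 5, base_sd_log2 = 1,
                       hybrid_bias_log2 = 0,
                       eld_mechanism = c("balanced", "partner"),
                       dosage_scale = FALSE, seed = 1L) {
  eld_mechanism <- match.arg(eld_mechanism)
  cats <- eld_categories(concrete_only = TRUE)
  if (is.null(category_mix))
    category_mix <- stats::setNames(rep(1 / length(cats), length(cats)),
                                    cats)
  if (is.null(names(category_mix)) ||
      !all(names(category_mix) %in% cats))
    stop("category_mix must be named with categories from ",
         "eld_categories(concrete_only = TRUE)")
  if (any(category_mix < 0))
    stop("category_mix proportions must be non-negative")
  if (abs(sum(category_mix) - 1) > 1e-9)
    stop("category_mix proportions must sum to 1 (got ",
         sum(category_mix), ")")
  if (!is.numeric(n_pairs) || n_pairs < 1)
    stop("n_pairs must be a positive integer")
  if (n_reps < 2)
    stop("n_reps must be at least 2")
  if (noise_sd_log2 <= 0)
    stop("noise_sd_log2 must be positive")
  if (effect_log2 <= 0)
    stop("effect_log2 must be positive")
  structure(list(n_pairs = as.integer(n_pairs), n_reps = as.integer(n_reps),
                 category_mix = category_mix, effect_log2 = effect_log2,
                 noise_sd_log2 = noise_sd_log2,
                 base_expr_log2 = base_expr_log2,
                 base_sd_log2 = base_sd_log2,
                 hybrid_bias_log2 = hybrid_bias_log2,
                 eld_mechanism = eld_mechanism,
                 dosage_scale = dosage_scale, seed = as.integer(seed)),
            class = "sim_config")
}

# split a pair total (log2) into the two homoeolog means at log2 ratio bias
split_total <- function(total_log2, bias_log2) {
  c(ar = total_log2 - log2(1 + 2^(-bias_log2)),
    o = total_log2 - log2(1 + 2^bias_log2))
}

#' Realize an ELD truth category as context means
#'
#' Chooses the four log2 context means (A^rp, O^p, A^rh, O^h) so that the
#' ELD decision table, evaluated on the exact means, yields the requested
#' category: dominance categories pin the hybrid pair total to one parent's
#' level with the parents separated by \code{effect_log2}; additivity puts
#' the total at the log-scale mid-parent; transgressive categories push the
#' total \code{effect_log2} beyond equal parents. Draws from the current
#' RNG stream (the high parent of an additive pair is chosen at random).
#'
#' @param eld_truth a concrete category
#'   (\code{eld_categories(concrete_only = TRUE)}).
#' @param config a \code{\link{sim_config}}.
#' @param base baseline log2 expression of the pair (default
#'   \code{config$base_expr_log2}).
#' @return Named numeric vector \code{c(ar_p, o_p, ar_h, o_h)} of log2
#'   means.
#' @export
realize_category <- function(eld_truth, config,
                             base = config$base_expr_log2) {
  stopifnot(inherits(config, "sim_config"))
  e <- config$effect_log2
  bias <- config$hybrid_bias_log2
  mech <- config$eld_mechanism
  hi <- base + e
  lo <- base
  split <- function(total) {
    s <- split_total(total, bias)
    c(ar_h = unname(s["ar"]), o_h = unname(s["o"]))
  }
  m <- switch(
    eld_truth,
    no_change = c(ar_p = base, o_p = base, split(base)),
    additivity = {
      p1_high <- stats::runif(1) < 0.5
      c(ar_p = if (p1_high) hi else lo,
        o_p = if (p1_high) lo else hi,
        split(base + e / 2))
    },
    ELD_P1_high =
      if (mech == "partner")
        c(ar_p = hi, o_p = lo, ar_h = hi, o_h = lo + e)
      else c(ar_p = hi, o_p = lo, split(hi)),
    ELD_P1_low =
      if (mech == "partner")
        c(ar_p = lo, o_p = hi, ar_h = lo, o_h = hi - e)
      else c(ar_p = lo, o_p = hi, split(lo)),
    ELD_P2_high = c(ar_p = lo, o_p = hi, split(hi)),
    ELD_P2_low = c(ar_p = hi, o_p = lo, split(lo)),
    transgressive_up = c(ar_p = base, o_p = base, split(base + e)),
    transgressive_down = c(ar_p = base, o_p = base, split(base - e)),
    stop("unsupported ELD category: ", eld_truth)
  )
  if (config$dosage_scale)
    m["o_h"] <- m["o_h"] - 1
  m
}

# exact-mean (noiseless) outcome of a two-group comparison
mean_outcome <- function(a, b, tol = 1e-9) {
  ifelse(abs(a - b) <= tol, "ns", ifelse(a > b, "greater", "less"))
}

# derive the consistent truth states implied by a set of context means
truth_from_means <- function(eld_truth, m) {
  sum_h <- log2(2^m[["ar_h"]] + 2^m[["o_h"]])
  hyb_state <- c(greater = "Ar_biased", less = "partner_biased",
                 ns = "unbiased")[[mean_outcome(m[["ar_h"]], m[["o_h"]])]]
  par_state <- c(greater = "Ar_biased", less = "partner_biased",
                 ns = "unbiased")[[mean_outcome(m[["ar_p"]], m[["o_p"]])]]
  chg <- c(greater = "up", ns = "unchanged", less = "down")
  ar_change <- chg[[mean_outcome(m[["ar_h"]], m[["ar_p"]])]]
  o_change <- chg[[mean_outcome(m[["o_h"]], m[["o_p"]])]]
  list(eld_truth = eld_truth,
       heb_truth = classify_heb(hyb_state, par_state),
       hybrid_state_truth = hyb_state, parental_state_truth = par_state,
       ar_change_truth = ar_change, partner_change_truth = o_change,
       linkage_truth = paste(ar_change, o_change, sep = ":"),
       sum_h_log2 = sum_h)
}

#' Simulate a three-species homoeolog expression experiment
#'
#' Generates replicate FPKM matrices for the diploid parent (A^r genes),
#' the tetraploid parent (A^n and C^n genes) and the triploid hybrid (all
#' three), a homoeolog pair list, and a per-pair truth table. Per-pair
#' baselines are N(base_expr_log2, base_sd_log2); every replicate value is
#' 2^(context mean + N(0, noise_sd_log2)). Identical configurations give
#' identical output.
#'
#' @param config a \code{\link{sim_config}}.
#' @return Object of class \code{"homeo_sim"}: list with
#'   \code{parent1}, \code{parent2}, \code{hybrid}
#'   (\code{\link{expression_matrix}} objects), \code{pairs} (data frame
#'   \code{ar_gene, partner_gene, partner_subgenome}), \code{truth} (one
#'   row per pair with the truth states and log2 context means) and
#'   \code{config}.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n <- config$n_pairs
  reps <- config$n_reps
  mix <- config$category_mix
  cats <- if (length(mix) == 1L) rep(names(mix), n)
    else sample(names(mix), n, replace = TRUE, prob = mix)
  partner_sub <- sample(c("An", "Cn"), n, replace = TRUE)
  bases <- stats::rnorm(n, config$base_expr_log2, config$base_sd_log2)
  ar_len <- sample(500:3000, n, replace = TRUE)
  o_len <- sample(500:3000, n, replace = TRUE)

  means <- matrix(NA_real_, n, 4,
                  dimnames = list(NULL, c("ar_p", "o_p", "ar_h", "o_h")))
  for (i in seq_len(n))
    means[i, ] <- realize_category(cats[i], config, base = bases[i])

  noise <- function(mean_vec)
    2^(mean_vec + matrix(stats::rnorm(n * reps, 0, config$noise_sd_log2),
                         n, reps))
  ar_p <- noise(means[, "ar_p"])
  o_p <- noise(means[, "o_p"])
  ar_h <- noise(means[, "ar_h"])
  o_h <- noise(means[, "o_h"])

  ar_genes <- sprintf("ArG%05d", seq_len(n))
  o_genes <- sprintf("%sG%05d", partner_sub, seq_len(n))

  parent1 <- expression_matrix(ar_p, ar_genes, rep("Ar", n), ar_len,
                               species = "AA", unit = "fpkm")
  parent2 <- expression_matrix(o_p, o_genes, partner_sub, o_len,
                               species = "AACC", unit = "fpkm")
  hybrid <- expression_matrix(rbind(ar_h, o_h),
                              c(ar_genes, o_genes),
                              c(rep("Ar", n), partner_sub),
                              c(ar_len, o_len),
                              species = "AAC", unit = "fpkm")

  pairs <- data.frame(ar_gene = ar_genes, partner_gene = o_genes,
                      partner_subgenome = partner_sub)
  truth_states <- lapply(seq_len(n), function(i)
    truth_from_means(cats[i], as.list(means[i, ])))
  truth <- data.frame(
    pair_id = paste(ar_genes, o_genes, sep = "|"),
    ar_gene = ar_genes, partner_gene = o_genes,
    partner_subgenome = partner_sub,
    eld_truth = cats,
    heb_truth = vapply(truth_states, `[[`, "", "heb_truth"),
    hybrid_state_truth = vapply(truth_states, `[[`, "",
                                "hybrid_state_truth"),
    parental_state_truth = vapply(truth_states, `[[`, "",
                                  "parental_state_truth"),
    ar_change_truth = vapply(truth_states, `[[`, "", "ar_change_truth"),
    partner_change_truth = vapply(truth_states, `[[`, "",
                                  "partner_change_truth"),
    linkage_truth = vapply(truth_states, `[[`, "", "linkage_truth"),
    ar_p_log2 = means[, "ar_p"], o_p_log2 = means[, "o_p"],
    ar_h_log2 = means[, "ar_h"], o_h_log2 = means[, "o_h"],
    sum_h_log2 = vapply(truth_states, `[[`, 0, "sum_h_log2"),
    row.names = NULL)

  structure(list(parent1 = parent1, parent2 = parent2, hybrid = hybrid,
                 pairs = pairs, truth = truth, config = config),
            class = "homeo_sim")
}

#' @export
print.homeo_sim <- function(x, ...) {
  cat(sprintf("homeo_sim: %d pairs, %d replicates, seed %d\n",
              x$config$n_pairs, x$config$n_reps, x$config$seed))
  print(table(x$truth$eld_truth))
  invisible(x)
}

#' Write a simulated experiment to TSV files
#'
#' Writes \code{parent1.tsv}, \code{parent2.tsv}, \code{hybrid.tsv} (matrix
#' format of \code{\link{write_expression_matrix}}), \code{pairs.tsv} and
#' \code{truth.tsv} into a directory.
#'
#' @param sim a \code{\link{simulate_experiment}} result.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "homeo_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(sim$parent1, file.path(dir, "parent1.tsv"))
  write_expression_matrix(sim$parent2, file.path(dir, "parent2.tsv"))
  write_expression_matrix(sim$hybrid, file.path(dir, "hybrid.tsv"))
  utils::write.table(sim$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
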