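# End-to-end orchestration: simulate (or load) -> QC -> pair-level HEB/ELD/
# linkage -> DEG -> optional enrichment, with TSV outputs, a JSON manifest
# and a plain-text report.

#' Pipeline configuration
#'
#' Collects every global threshold of the analysis with its conventional
#' default: pair-test significance level 0.05, DEG |log2FC| threshold 2,
#' reciprocal-best-hit e-value cutoff 1e-20, expressed-pair FPKM floor 1.
#' Input is either a \code{\link{sim_config}} (simulation mode) or paths to
#' the three matrix TSVs plus a pair-list TSV.
#'
#' @param sim optional \code{\link{sim_config}}; when given, inputs are
#'   simulated.
#' @param parent1,parent2,hybrid paths to expression-matrix TSVs (ignored
#'   in simulation mode).
#' @param pairs path to a homoeolog-pair TSV with columns
#'   \code{ar_gene, partner_gene, partner_subgenome}.
#' @param annotation optional path to a gene-term TSV
#'   (\code{gene_id, term_id[, term_name]}) for DEG enrichment.
#' @param alpha significance level for all pair-level t-tests.
#' @param lfc absolute log2 fold-change DEG threshold.
#' @param e_cutoff reciprocal-best-hit e-value cutoff (kept in the manifest
#'   even when pairing is done upstream).
#' @param expr_floor expressed-pair mean-FPKM floor.
#' @param out_dir output directory.
#' @param seed integer seed for any randomness in the run.
#' @return Object of class \code{"run_config"}.
#' @export
run_config <- function(sim = NULL, parent1 = NULL, parent2 = NULL,
                       hybrid = NULL, pairs = NULL, annotation = NULL,
                       alpha = 0.05, lfc = 2, e_cutoff = 1e-20,
                       expr_floor = 1, out_dir = tempfile("homeoshock_run"),
                       seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (lfc <= 0) stop("lfc threshold must be positive")
  if (e_cutoff <= 0) stop("e_cutoff must be positive")
  if (expr_floor < 0) stop("expr_floor must be non-negative")
  if (is.null(sim) &&
      (is.null(parent1) || is.null(parent2) || is.null(hybrid) ||
       is.null(pairs)))
    stop("either a sim config or the three matrix paths plus pairs ",
         "must be given")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, parent1 = parent1, parent2 = parent2,
                 hybrid = hybrid, pairs = pairs, annotation = annotation,
                 alpha = alpha, lfc = lfc, e_cutoff = e_cutoff,
                 expr_floor = expr_floor, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) the three expression matrices and the pair list,
#' computes sample QC (replicate Spearman correlation and a PCA of all
#' samples on pair-level expression), filters pairs by the expressed floor,
#' calls HEB, ELD and mechanism linkage, calls DEGs of the hybrid against
#' each parent, optionally runs term enrichment on the DEG set, and writes
#' every stage table plus a JSON manifest under \code{config$out_dir}.
#' Deterministic for a fixed config and seed.
#'
#' @param config a \code{\link{run_config}}.
#' @return List with the stage outputs (\code{sim} or input data,
#'   \code{qc}, \code{pe}, \code{heb}, \code{eld}, \code{linkage},
#'   \code{summaries}, \code{deg}, \code{enrichment}, \code{confusion},
#'   \code{manifest}) and \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed # the run seed governs the simulation
    sim <- do.call(sim_config, unclass(sim))
    data <- simulate_experiment(sim)
    write_simulation(data, file.path(config$out_dir, "input"))
    pairs <- data$pairs
    truth <- data$truth
  } else {
    data <- list(
      parent1 = read_expression_matrix(config$parent1, species = "AA"),
      parent2 = read_expression_matrix(config$parent2, species = "AACC"),
      hybrid = read_expression_matrix(config$hybrid, species = "AAC"))
    pairs <- utils::read.delim(config$pairs, stringsAsFactors = FALSE)
    truth <- NULL
  }

  pe_all <- pair_expression(pairs, data$parent1, data$parent2, data$hybrid)
  pe <- filter_expressed(pe_all, config$expr_floor)
  if (!nrow(pe$pairs))
    stop("stage 'filter_expressed' failed: no pair passes the FPKM floor")

  # sample QC on pair-level expression: every pair seen in all 9 samples
  # (A^r in parent1, partner in parent2, pair total in the hybrid)
  qc_mat <- cbind(pe_all$ar_p, pe_all$o_p, pe_all$ar_h + pe_all$o_h)
  colnames(qc_mat) <- c(paste0("P1_", colnames(pe_all$ar_p)),
                        paste0("P2_", colnames(pe_all$o_p)),
                        paste0("H_", colnames(pe_all$ar_h)))
  qc <- list(correlation = sample_correlation(qc_mat),
             pca = pca_embedding(qc_mat, k = 2L))
  write_tsv(as.data.frame(qc$correlation),
            file.path(config$out_dir, "qc_correlation.tsv"))
  write_tsv(data.frame(sample = rownames(qc$pca), qc$pca),
            file.path(config$out_dir, "qc_pca.tsv"))

  heb <- heb_calls(pe, config$alpha)
  eld <- eld_calls(pe, config$alpha)
  linkage <- linkage_calls(pe, config$alpha)
  summaries <- list(heb = heb_summary(heb),
                    eld = eld_summary(eld, linkage))
  write_tsv(heb, file.path(config$out_dir, "heb_calls.tsv"))
  write_tsv(eld, file.path(config$out_dir, "eld_calls.tsv"))
  write_tsv(linkage, file.path(config$out_dir, "linkage_calls.tsv"))
  write_tsv(summaries$heb, file.path(config$out_dir, "heb_summary.tsv"))
  write_tsv(summaries$eld$category,
            file.path(config$out_dir, "eld_summary.tsv"))

  deg <- list(hybrid_vs_parent1 = deg_table(data$hybrid, data$parent1,
                                            lfc = config$lfc,
                                            alpha = config$alpha),
              hybrid_vs_parent2 = deg_table(data$hybrid, data$parent2,
                                            lfc = config$lfc,
                                            alpha = config$alpha))
  write_tsv(deg$hybrid_vs_parent1,
            file.path(config$out_dir, "deg_hybrid_vs_parent1.tsv"))
  write_tsv(deg$hybrid_vs_parent2,
            file.path(config$out_dir, "deg_hybrid_vs_parent2.tsv"))

  enrichment <- NULL
  if (!is.null(config$annotation)) {
    anno <- utils::read.delim(config$annotation, stringsAsFactors = FALSE)
    deg_set <- unique(unlist(lapply(deg, function(d)
      d$gene_id[d$call != "ns"])))
    enrichment <- enrich(deg_set, anno, alpha = 0.05)
    write_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"))
  }

  confusion <- NULL
  if (!is.null(truth)) {
    truth_f <- truth[match(pe$pairs$pair_id, truth$pair_id), , drop = FALSE]
    confusion <- table(truth = truth_f$eld_truth, call = eld$category)
    write_tsv(as.data.frame(confusion),
              file.path(config$out_dir, "eld_confusion.tsv"))
  }

  manifest <- list(
    package = "homeoshock",
    version = as.character(utils::packageVersion("homeoshock")),
    seed = config$seed,
    thresholds = list(alpha = config$alpha, lfc = config$lfc,
                      e_cutoff = config$e_cutoff,
                      expr_floor = config$expr_floor),
    simulated = !is.null(config$sim),
    sim_config = if (!is.null(config$sim))
      unclass(do.call(sim_config,
                      utils::modifyList(unclass(config$sim),
                                        list(seed = config$seed)))),
    counts = list(pairs_total = nrow(pe_all$pairs),
                  pairs_expressed = nrow(pe$pairs),
                  heb_calls = nrow(heb), eld_calls = nrow(eld),
                  linkage_calls = nrow(linkage),
                  deg_hybrid_vs_parent1 =
                    sum(deg$hybrid_vs_parent1$call != "ns"),
                  deg_hybrid_vs_parent2 =
                    sum(deg$hybrid_vs_parent2$call != "ns")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(data = data, truth = truth, qc = qc, pe = pe, heb = heb,
                 eld = eld, linkage = linkage, summaries = summaries,
                 deg = deg, enrichment = enrichment, confusion = confusion,
                 manifest = manifest, out_dir = config$out_dir),
            class = "homeo_run")
}

fmt_table <- function(tab) {
  out <- utils::capture.output(print(tab))
  paste0("  ", out)
}

#' Write a human-readable run report
#'
#' Summarizes a pipeline run: expression bins and expressed-gene Venn
#' overlap of the three materials, HEB and ELD category proportions,
#' linkage 3x3 tables per ELD category, DEG counts, and (when simulation
#' truth is available) the truth-vs-call confusion matrix with the exact
#' recovery rate. The report is written to \code{report.txt} in the run's
#' output directory.
#'
#' @param run a \code{\link{run_pipeline}} result.
#' @return Character vector of report lines, invisibly.
#' @export
write_report <- function(run) {
  stopifnot(inherits(run, "homeo_run"))
  for (stage in c("heb", "eld", "linkage", "summaries"))
    if (is.null(run[[stage]]) ||
        (is.data.frame(run[[stage]]) && !nrow(run[[stage]])))
      stop("missing stage output: ", stage)
  if (!nrow(run$eld)) stop("missing stage output: eld")
  lines <- c("homeoshock run report", "=====================", "")

  mats <- list(parent1 = run$data$parent1, parent2 = run$data$parent2,
               hybrid = run$data$hybrid)
  lines <- c(lines, "Expression bins (mean FPKM per gene):")
  for (nm in names(mats)) {
    bins <- table(bin_by_expression(rowMeans(mats[[nm]]$values)))
    lines <- c(lines, sprintf("  %s: %s", nm,
                              paste(sprintf("%s=%d", names(bins), bins),
                                    collapse = "  ")))
  }
  floor <- run$manifest$thresholds$expr_floor
  expressed <- lapply(mats, function(m)
    m$genes$gene_id[rowMeans(m$values) >= floor])
  names(expressed) <- c("P1", "P2", "H")
  ov <- overlap_counts(expressed)
  lines <- c(lines, "",
             sprintf("Expressed genes (mean FPKM >= %g), Venn regions:",
                     floor),
             sprintf("  %s = %d", names(ov$regions), ov$regions))

  lines <- c(lines, "", "HEB category proportions:")
  hs <- run$summaries$heb
  heb_cat <- tapply(hs$n, hs$category, sum)
  lines <- c(lines, sprintf("  %s: %d (%.1f%%)", names(heb_cat), heb_cat,
                            100 * heb_cat / sum(heb_cat)))

  lines <- c(lines, "", "ELD category proportions:")
  es <- run$summaries$eld$category
  eld_cat <- tapply(es$n, es$category, sum)
  lines <- c(lines, sprintf("  %s: %d (%.1f%%)", names(eld_cat), eld_cat,
                            100 * eld_cat / sum(eld_cat)))
  stopifnot(sum(eld_cat) == nrow(run$eld),
            sum(heb_cat) == nrow(run$heb))

  lines <- c(lines, "",
             "Linkage (A^r change x partner change) per ELD category:")
  for (nm in names(run$summaries$eld$linkage)) {
    lines <- c(lines, sprintf("  [%s]", nm),
               fmt_table(run$summaries$eld$linkage[[nm]]))
  }

  lines <- c(lines, "", "DEG counts (hybrid vs parents):")
  for (nm in names(run$deg)) {
    calls <- table(factor(run$deg[[nm]]$call, c("up", "down", "ns")))
    lines <- c(lines, sprintf("  %s: up=%d down=%d ns=%d", nm,
                              calls[["up"]], calls[["down"]],
                              calls[["ns"]]))
  }

  if (!is.null(run$confusion)) {
    common <- intersect(rownames(run$confusion), colnames(run$confusion))
    rec <- sum(run$confusion[cbind(common, common)]) / sum(run$confusion)
    lines <- c(lines, "", "ELD truth-vs-call confusion:",
               fmt_table(run$confusion),
               sprintf("  exact category recovery: %.3f", rec))
  }

  writeLines(lines, file.path(run$out_dir, "report.txt"))
  invisible(lines)
}
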