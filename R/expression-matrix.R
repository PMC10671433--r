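#' Expression matrix with per-gene subgenome labels
#'
#' The common currency of the pipeline: a genes x samples abundance table
#' (raw counts or FPKM) together with a subgenome label (\code{"Ar"},
#' \code{"An"} or \code{"Cn"}) and a transcript length in bp for every gene,
#' and a species tag for the whole matrix (\code{"AA"} for the diploid
#' parent, \code{"AACC"} for the tetraploid parent, \code{"AAC"} for the
#' triploid hybrid).
#'
#' @param values numeric matrix, genes x samples, non-negative.
#' @param gene_id character vector of unique gene identifiers (row names).
#' @param subgenome character vector, one of \code{"Ar"}, \code{"An"},
#'   \code{"Cn"} per gene.
#' @param length_bp positive integer vector of transcript lengths.
#' @param species species tag, one of \code{"AA"}, \code{"AACC"},
#'   \code{"AAC"}.
#' @param unit abundance unit, \code{"fpkm"} or \code{"counts"}.
#' @return An object of class \code{"expression_matrix"}: a list with
#'   elements \code{values} (matrix with gene ids as row names),
#'   \code{genes} (data frame with \code{gene_id}, \code{subgenome},
#'   \code{length_bp}), \code{species} and \code{unit}.
#' @export
expression_matrix <- function(values, gene_id, subgenome, length_bp,
                              species = c("AA", "AACC", "AAC"),
                              unit = c("fpkm", "counts")) {
  species <- match.arg(species)
  unit <- match.arg(unit)
  values <- as.matrix(values)
  gene_id <- as.character(gene_id)
  subgenome <- as.character(subgenome)
  if (nrow(values) != length(gene_id))
    stop("values has ", nrow(values), " rows but ", length(gene_id),
         " gene ids were given")
  if (ncol(values) < 1L)
    stop("at least one sample column is required")
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (length(subgenome) != length(gene_id) ||
      length(length_bp) != length(gene_id))
    stop("gene_id, subgenome and length_bp must have equal length")
  if (!all(subgenome %in% c("Ar", "An", "Cn")))
    stop("subgenome labels must be one of 'Ar', 'An', 'Cn'")
  if (any(!is.finite(length_bp)) || any(length_bp <= 0))
    stop("gene lengths must be positive and finite")
  if (any(!is.finite(values)) || any(values < 0))
    stop("abundance values must be non-negative and finite")
  rownames(values) <- gene_id
  if (is.null(colnames(values)))
    colnames(values) <- paste0("rep", seq_len(ncol(values)))
  structure(
    list(values = values,
         genes = data.frame(gene_id = gene_id, subgenome = subgenome,
                            length_bp = as.numeric(length_bp)),
         species = species, unit = unit),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s, %s)\n",
              nrow(x$values), ncol(x$values), x$species, x$unit))
  tab <- table(x$genes$subgenome)
  cat("  subgenomes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Expects a header line \code{gene_id, subgenome, length_bp} followed by one
#' column per sample.
#'
#' @param path path to a tab-separated file.
#' @param species species tag for the matrix (see
#'   \code{\link{expression_matrix}}).
#' @param unit abundance unit of the stored values.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression_matrix <- function(path, species, unit = "fpkm") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("gene_id", "subgenome", "length_bp")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("format error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  sample_cols <- setdiff(names(df), required)
  if (!length(sample_cols))
    stop("format error in ", path, ": no sample columns after ",
         "gene_id/subgenome/length_bp")
  dup <- duplicated(df$gene_id)
  if (any(dup))
    stop("format error in ", path, ": duplicate gene_id '",
         df$gene_id[dup][1], "' at line ", which(dup)[1] + 1L)
  vals <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(vals))
    stop("format error in ", path, ": non-numeric abundance values")
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("format error in ", path, ": negative value at line ",
         neg[1, 1] + 1L)
  expression_matrix(vals, df$gene_id, df$subgenome, df$length_bp,
                    species = species, unit = unit)
}

#' Write an expression matrix as TSV
#'
#' @param em an \code{\link{expression_matrix}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- cbind(em$genes, as.data.frame(em$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert raw counts to FPKM
#'
#' FPKM\code{[g,s] = count[g,s] / ((length_bp[g]/1e3) * (libsize[s]/1e6))}
#' where the library size is the column sum of the count matrix. A sample
#' with zero total counts yields an all-zero column with a warning.
#'
#' @param em an \code{\link{expression_matrix}} in \code{"counts"} unit.
#' @return An \code{\link{expression_matrix}} in \code{"fpkm"} unit.
#' @export
compute_fpkm <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$unit != "counts")
    stop("compute_fpkm expects a counts-mode matrix")
  libsize <- colSums(em$values)
  zero <- libsize == 0
  if (any(zero)) {
    warning("zero library size in sample(s): ",
            paste(colnames(em$values)[zero], collapse = ", "))
    libsize[zero] <- 1 # counts are all zero there, so FPKM stays zero
  }
  kb <- em$genes$length_bp / 1e3
  fpkm <- sweep(em$values / kb, 2, libsize / 1e6, "/")
  out <- em
  out$values <- fpkm
  out$unit <- "fpkm"
  out
}

#' Bin genes by expression level
#'
#' Assigns every gene to one of the four half-open FPKM bins
#' \code{[0,1)}, \code{[1,10)}, \code{[10,100)}, \code{[100,Inf)} used to
#' stratify expressed genes across the parents and the hybrid.
#'
#' @param mean_fpkm non-negative numeric vector of per-gene mean FPKM
#'   (replicate mean).
#' @return Factor with the four bin labels as levels.
#' @export
bin_by_expression <- function(mean_fpkm) {
  if (any(!is.finite(mean_fpkm)) || any(mean_fpkm < 0))
    stop("mean_fpkm must be non-negative and finite")
  cut(mean_fpkm, breaks = c(0, 1, 10, 100, Inf), right = FALSE,
      labels = c("[0,1)", "[1,10)", "[10,100)", "[100,Inf)"))
}

#' Three-set Venn region counts
#'
#' Counts the seven regions of the Venn diagram of three gene-id sets (the
#' per-bin membership of parent 1, hybrid and parent 2).
#'
#' @param sets named list of three character vectors.
#' @return A list with \code{regions} (named integer vector, the 7 exclusive
#'   regions keyed by set-name combinations such as \code{"AA&AAC"}),
#'   \code{totals} (per-set sizes) and \code{union} (union size; always
#'   equals \code{sum(regions)}).
#' @export
overlap_counts <- function(sets) {
  stopifnot(is.list(sets), length(sets) == 3L)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- c("A", "B", "C")
  sets <- lapply(sets, function(x) unique(as.character(x)))
  all_ids <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (length(all_ids) == 0L)
    member <- matrix(logical(0), 0, 3, dimnames = list(NULL, names(sets)))
  key <- apply(member, 1L, function(m) paste(names(sets)[m], collapse = "&"))
  combos <- unlist(lapply(1:3, function(k)
    utils::combn(names(sets), k, paste, collapse = "&")))
  regions <- stats::setNames(integer(length(combos)), combos)
  tab <- table(key)
  regions[names(tab)] <- as.integer(tab)
  list(regions = regions,
       totals = vapply(sets, length, integer(1)),
       union = length(all_ids))
}

#' Sample-sample Spearman correlation
#'
#' Rank correlation between all sample columns, the replicate-consistency QC
#' used before any pair-level analysis. Pairs involving a constant column
#' have undefined rank correlation and are reported as \code{NA}.
#'
#' @param em an \code{\link{expression_matrix}} (or plain genes x samples
#'   matrix) with at least two samples.
#' @param method correlation method, default \code{"spearman"}.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(em, method = "spearman") {
  vals <- if (inherits(em, "expression_matrix")) em$values else as.matrix(em)
  if (ncol(vals) < 2L)
    stop("at least 2 samples are required")
  cc <- suppressWarnings(stats::cor(vals, method = method))
  diag(cc) <- 1
  cc
}

#' PCA embedding of samples
#'
#' Principal components of the samples computed on log10(FPKM + 1)
#' transformed values, the transform used for global expression heatmaps.
#'
#' @param em an \code{\link{expression_matrix}} (FPKM) or plain genes x
#'   samples matrix.
#' @param k number of components to return (capped at the available rank).
#' @return Matrix of sample coordinates, samples x k, with the per-component
#'   proportion of variance as attribute \code{"var_explained"}.
#' @export
pca_embedding <- function(em, k = 2L) {
  vals <- if (inherits(em, "expression_matrix")) em$values else as.matrix(em)
  if (ncol(vals) < 2L)
    stop("at least 2 samples are required")
  pc <- stats::prcomp(t(log10p1(vals)), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  attr(coords, "var_explained") <- ve[seq_len(k)]
  coords
}
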