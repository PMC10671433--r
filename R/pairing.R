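# Homoeolog pairing by reciprocal best BLAST hits between subgenomes.

#' Read tabular BLAST output (outfmt 6)
#'
#' Parses the standard 12-column tab-separated BLAST format:
#' query, subject, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, e-value, bit score.
#'
#' @param path path to a BLAST outfmt-6 file.
#' @return Data frame with columns \code{query_id}, \code{subject_id},
#'   \code{percent_identity}, \code{alignment_length}, \code{e_value},
#'   \code{bit_score}.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(),
                      alignment_length = integer(),
                      e_value = numeric(), bit_score = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad))
    stop("format error in ", path, ": line ", bad[1], " has ", nf[bad[1]],
         " columns (12 expected)")
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  evalue <- suppressWarnings(as.numeric(m[, 11]))
  bits <- suppressWarnings(as.numeric(m[, 12]))
  bad <- which(is.na(evalue) | is.na(bits) | evalue < 0 | !is.finite(bits))
  if (length(bad))
    stop("format error in ", path, ": non-numeric e-value/bit score at line ",
         bad[1])
  data.frame(query_id = m[, 1], subject_id = m[, 2],
             percent_identity = suppressWarnings(as.numeric(m[, 3])),
             alignment_length = suppressWarnings(as.integer(m[, 4])),
             e_value = evalue, bit_score = bits)
}

#' Best hit per query
#'
#' Drops hits above the e-value threshold, then keeps for every query the
#' single subject with the highest bit score; ties are broken by lower
#' e-value, then by lexicographically smallest subject id. Self-hits
#' (query == subject) are removed by default since homoeolog pairing is a
#' cross-subgenome (bipartite) matching.
#'
#' @param hits data frame as returned by \code{\link{read_blast_tab}}.
#' @param e_cutoff maximum e-value retained (default \code{1e-20}).
#' @param exclude_self drop hits with \code{query_id == subject_id}.
#' @return Data frame with one row per query: \code{query_id},
#'   \code{subject_id}, \code{e_value}, \code{bit_score}.
#' @export
best_hits <- function(hits, e_cutoff = 1e-20, exclude_self = TRUE) {
  stopifnot(is.numeric(e_cutoff), e_cutoff > 0)
  keep <- hits$e_value <= e_cutoff
  if (exclude_self)
    keep <- keep & hits$query_id != hits$subject_id
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits))
    return(hits[, c("query_id", "subject_id", "e_value", "bit_score")])
  ord <- order(hits$query_id, -hits$bit_score, hits$e_value,
               hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  first <- !duplicated(hits$query_id)
  out <- hits[first, c("query_id", "subject_id", "e_value", "bit_score")]
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits
#'
#' A pair (q, s) is kept iff q's best forward hit is s and s's best reverse
#' hit is q — the bidirectional best-hit definition of homoeology. Each gene
#' occurs in at most one pair per subgenome pairing.
#'
#' @param forward best-hit table (\code{\link{best_hits}}) with parent-1
#'   (A^r) genes as queries.
#' @param reverse best-hit table with partner-subgenome genes as queries.
#' @param partner_subgenome label attached to every pair, \code{"An"} or
#'   \code{"Cn"}.
#' @return Data frame sorted by \code{ar_gene} with columns \code{ar_gene},
#'   \code{partner_gene}, \code{partner_subgenome}, \code{fwd_e_value},
#'   \code{fwd_bit_score}, \code{rev_e_value}, \code{rev_bit_score}.
#' @export
reciprocal_best_hits <- function(forward, reverse,
                                 partner_subgenome = c("An", "Cn")) {
  partner_subgenome <- match.arg(partner_subgenome)
  rev_map <- stats::setNames(reverse$subject_id, reverse$query_id)
  keep <- !is.na(rev_map[forward$subject_id]) &
    rev_map[forward$subject_id] == forward$query_id
  fwd <- forward[keep, , drop = FALSE]
  ridx <- match(fwd$subject_id, reverse$query_id)
  out <- data.frame(ar_gene = fwd$query_id,
                    partner_gene = fwd$subject_id,
                    partner_subgenome = rep(partner_subgenome,
                                            nrow(fwd)),
                    fwd_e_value = fwd$e_value,
                    fwd_bit_score = fwd$bit_score,
                    rev_e_value = reverse$e_value[ridx],
                    rev_bit_score = reverse$bit_score[ridx])
  out <- out[order(out$ar_gene), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$ar_gene), !anyDuplicated(out$partner_gene))
  out
}

#' Derive homoeolog pairs from two BLAST tabular files
#'
#' Convenience wrapper: read both directions, take best hits at the e-value
#' threshold, intersect reciprocally.
#'
#' @param forward_path BLAST outfmt-6 file, A^r proteins vs partner
#'   subgenome.
#' @param reverse_path BLAST outfmt-6 file, partner subgenome vs A^r.
#' @param partner_subgenome \code{"An"} or \code{"Cn"}.
#' @param e_cutoff maximum e-value (default \code{1e-20}).
#' @return Pair table as in \code{\link{reciprocal_best_hits}}.
#' @export
homoeolog_pairs <- function(forward_path, reverse_path,
                            partner_subgenome = c("An", "Cn"),
                            e_cutoff = 1e-20) {
  fwd <- best_hits(read_blast_tab(forward_path), e_cutoff)
  rev <- best_hits(read_blast_tab(reverse_path), e_cutoff)
  reciprocal_best_hits(fwd, rev, partner_subgenome)
}
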