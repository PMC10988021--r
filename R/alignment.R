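# Protein pairwise alignment: Smith-Waterman (homology screen) and
# Needleman-Wunsch (percent identity/similarity), BLOSUM62, affine gaps.
# A gap of length L costs open + (L - 1) * ext.

.blosum_cache <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix restricted to the 20 residues + X
#'
#' @return numeric 21 x 21 substitution matrix.
#' @export
blosum62 <- function() {
  m <- .blosum_cache$m
  if (is.null(m)) {
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    keep <- c(AA20, "X")
    m <- e$BLOSUM62[keep, keep]
    .blosum_cache$m <- m
  }
  m
}

#' Align two proteins with local (Smith-Waterman) alignment
#'
#' BLOSUM62 scoring with affine gaps (default open 11, extend 1, the blastp
#' defaults). Identity is identical pairs over alignment columns; coverage is
#' aligned reference residues over reference length. Tie-breaking is
#' deterministic (highest score, diagonal-preferring traceback, leftmost
#' maximal cell).
#'
#' @param query,reference amino-acid strings (20 standard residues + X).
#' @param gap_open,gap_extend gap penalties (positive).
#' @param mode `"local"` or `"global"`.
#' @return list with `score`, `identity`, `coverage`, `similarity` (positive
#'   BLOSUM62 pairs over columns), alignment strings and 1-based spans.
#' @export
align_proteins <- function(query, reference, gap_open = 11, gap_extend = 1,
                           mode = c("local", "global")) {
  mode <- match.arg(mode)
  assert_protein(query, "query")
  assert_protein(reference, "reference")
  m <- blosum62()
  r <- cpp_align(query, reference, m, paste(colnames(m), collapse = ""),
                 gap_open, gap_extend, mode == "local")
  cols <- max(r$n_columns, 1L)
  list(score = r$score,
       identity = r$n_identical / cols,
       similarity = r$n_positive / cols,
       coverage = r$n_ref_aligned / nchar(reference),
       query_aln = r$query_aln, ref_aln = r$ref_aln,
       q_start = r$q_start, q_end = r$q_end,
       r_start = r$r_start, r_end = r$r_end,
       n_columns = r$n_columns)
}

#' Global percent identity and similarity between two peptides
#'
#' Needleman-Wunsch with BLOSUM62, gap open 10 / extend 0.5. Identity is
#' identical pairs over alignment length; similarity counts pairs with a
#' positive BLOSUM62 score (the usual "similar residues" convention; the
#' field's tools differ here, so reported similarities are approximate).
#'
#' @param a,b amino-acid strings.
#' @return list with `identity` and `similarity`, both percentages in
#'   `[0, 100]`.
#' @export
percent_similarity <- function(a, b) {
  r <- align_proteins(a, b, gap_open = 10, gap_extend = 0.5, mode = "global")
  list(identity = 100 * r$identity, similarity = 100 * r$similarity)
}
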