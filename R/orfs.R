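# Six-frame open reading frame scanning.
#
# For every contig and both strands, each of the three frames is walked codon
# by codon; between consecutive stop codons the maximal ORF starts at the
# first ATG/GTG/TTG start codon. Coordinates are reported on the forward
# strand, 0-based half-open, and include the stop codon when present; ORFs
# running off the contig edge are kept (translation ends at the edge).

START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames in all six frames
#'
#' @param assembly named character vector of contig sequences (A, C, G, T, N).
#' @param min_orf_len minimum translated length in amino acids (default 50).
#' @return data.frame with columns contig, start, end (0-based half-open,
#'   forward strand), strand, frame (0-2 on the reading strand), length_aa,
#'   protein.
#' @export
find_orfs <- function(assembly, min_orf_len = 50L) {
  stopifnot(length(assembly) >= 1L, min_orf_len >= 1L)
  if (is.null(names(assembly))) names(assembly) <- paste0("contig_", seq_along(assembly))
  out <- list()
  for (ctg in names(assembly)) {
    seq_fwd <- toupper(assembly[[ctg]])
    bad <- regexpr("[^ACGTN]", seq_fwd)
    if (bad > 0)
      stop("non-ACGTN character in contig '", ctg, "' at offset ", bad - 1L)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq_fwd else revcomp(seq_fwd)
      L <- nchar(s)
      for (frame in 0:2) {
        n_codon <- (L - frame) %/% 3L
        if (n_codon < 1L) next
        starts_nt <- frame + 3L * (seq_len(n_codon) - 1L) + 1L
        codons <- substring(s, starts_nt, starts_nt + 2L)
        is_stop <- codons %in% STOP_CODONS
        is_start <- codons %in% START_CODONS
        block_begin <- 1L
        bounds <- c(which(is_stop), n_codon + 1L) # sentinel: contig edge
        for (b in bounds) {
          if (b > n_codon && block_begin > n_codon) break
          cand <- block_begin:min(b, n_codon)
          st <- cand[is_start[cand]]
          if (length(st)) {
            first <- st[1]
            last <- min(b, n_codon)          # stop codon included if present
            len_aa <- (if (b <= n_codon) b - first else last - first + 1L)
            if (len_aa >= min_orf_len) {
              nt_from <- frame + 3L * (first - 1L)        # 0-based on strand s
              nt_to <- frame + 3L * last                  # half-open, incl. stop
              if (strand == "+") {
                fs <- nt_from; fe <- nt_to
              } else {
                fs <- L - nt_to; fe <- L - nt_from
              }
              prot <- paste(ifelse(grepl("N", codons[first:last]), "X",
                                   Biostrings::GENETIC_CODE[codons[first:last]]),
                            collapse = "")
              prot <- sub("\\*$", "", prot)
              out[[length(out) + 1L]] <- data.frame(
                contig = ctg, start = fs, end = fe, strand = strand,
                frame = frame, length_aa = nchar(prot), protein = prot,
                stringsAsFactors = FALSE)
            }
          }
          block_begin <- b + 1L
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      length_aa = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}
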