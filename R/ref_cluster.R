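# Bundled SYNTHETIC epilancin reference cluster.
#
# The nine-gene epilancin cluster encodes the precursor peptide (elaA), a
# protease (elaP), the dehydratase (elaB) and cyclase (elaC) tailoring
# enzymes, a transporter (elaT), the leader-peptidase/dehydrogenase (elaO)
# responsible for the N-terminal lactate, and three putative immunity
# proteins (elaI1/I2/I3). The deposited producer genomes are not bundled, so
# the reference proteins here are SYNTHETIC: elaA is hand-designed to carry
# an epilancin-like 30-residue core with the canonical ring topology
# (11-residue linear N-terminus, 5-residue ring A, 3-residue hinge, two
# intertwined 4-residue rings spanning 5 residues, 6-residue tail); the
# remaining proteins are fixed pseudo-random sequences of plausible (scaled)
# lengths, deterministic under a frozen internal seed.

#' Reference cluster constants
#'
#' `ELA_GENES` is the canonical gene order of the bundled synthetic epilancin
#' cluster; `ELA_LEADER` and `ELA_CORE` are the leader (25 aa) and core
#' (30 aa) segments of the synthetic elaA precursor.
#'
#' @format `ELA_GENES` a character vector of nine gene names; `ELA_LEADER`
#'   and `ELA_CORE` single amino-acid strings.
#' @export
ELA_GENES <- c("elaA", "elaP", "elaB", "elaC", "elaT", "elaO",
               "elaI1", "elaI2", "elaI3")

#' @rdname ELA_GENES
#' @export
ELA_LEADER <- "MENKKDLFDLEIKKDTMQNAASSPQ"                # 25 aa

#' @rdname ELA_GENES
#' @export
ELA_CORE   <- "SASIVKTTIKASKKLCRGFTSGCCHFTGKK"          # 30 aa

# Most-frequent-codon back-translation table (AT-rich staphylococcal choice;
# any fixed table works because mining operates at the protein level).
ELA_CODON <- c(
  A = "GCA", R = "AGA", N = "AAT", D = "GAT", C = "TGT",
  Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
  L = "TTA", K = "AAA", M = "ATG", F = "TTT", P = "CCA",
  S = "TCA", T = "ACA", W = "TGG", Y = "TAT", V = "GTT",
  X = "NNN", `*` = "TAA")

ref_protein_lengths <- c(elaP = 290L, elaB = 600L, elaC = 440L, elaT = 520L,
                         elaO = 310L, elaI1 = 120L, elaI2 = 140L, elaI3 = 85L)

#' The bundled synthetic epilancin reference cluster
#'
#' @return a list with elements `genes` (reference gene order), `proteins`
#'   (named character vector, amino acids), `cds` (named character vector,
#'   back-translated coding sequences including the stop codon), `leader` and
#'   `core` (the elaA precursor split), and `codon_table`.
#' @export
ela_reference <- function() {
  ref <- .ela_ref_cache$ref
  if (!is.null(ref)) return(ref)
  prots <- c(elaA = paste0(ELA_LEADER, ELA_CORE))
  # residue frequencies loosely matching a staphylococcal proteome
  aa_freq <- c(A = .08, C = .01, D = .06, E = .07, F = .04, G = .07, H = .02,
               I = .08, K = .08, L = .10, M = .02, N = .05, P = .03, Q = .04,
               R = .04, S = .06, T = .06, V = .07, W = .01, Y = .04)
  body <- with_seed(920319L, {
    lapply(ref_protein_lengths, function(n) {
      paste0("M", paste(sample(names(aa_freq), n - 1L, replace = TRUE,
                               prob = aa_freq), collapse = ""))
    })
  })
  prots <- c(prots, unlist(body))
  prots <- prots[ELA_GENES]
  cds <- vapply(prots, back_translate, character(1))
  ref <- list(genes = ELA_GENES, proteins = prots, cds = cds,
              leader = ELA_LEADER, core = ELA_CORE, codon_table = ELA_CODON)
  .ela_ref_cache$ref <- ref
  ref
}
.ela_ref_cache <- new.env(parent = emptyenv())

#' Back-translate a protein with the fixed codon table
#'
#' Appends a TAA stop codon.
#'
#' @param protein amino-acid string.
#' @return DNA string.
#' @export
back_translate <- function(protein) {
  assert_protein(protein, "protein")
  aa <- strsplit(protein, "")[[1]]
  paste0(paste(ELA_CODON[aa], collapse = ""), "TAA")
}

#' Translate a DNA sequence with the standard genetic code
#'
#' Translation stops at the first stop codon; incomplete trailing codons are
#' dropped; codons containing N translate to X.
#'
#' @param dna DNA string.
#' @param to_stop stop at the first stop codon (default TRUE).
#' @return amino-acid string (stop excluded).
#' @export
translate_dna <- function(dna, to_stop = TRUE) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  if (to_stop) {
    s <- which(aa == "*")
    if (length(s)) aa <- aa[seq_len(s[1] - 1L)]
  } else {
    aa[aa == "*"] <- "*"
  }
  paste(aa, collapse = "")
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}
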