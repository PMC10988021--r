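# Small shared helpers: scoped RNG, FASTA I/O shims, validation.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global RNG state so that seeded generators inside the
#' package do not disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Write named sequences to a FASTA file
#'
#' @param seqs named character vector of sequences (DNA or protein).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "wb") # binary mode: byte-identical output across platforms
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path input file path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standard 20-residue alphabet
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

assert_protein <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop(what, " must be a non-empty amino-acid string")
  bad <- setdiff(strsplit(seq, "")[[1]], c(AA20, "X"))
  if (length(bad))
    stop(what, " contains non-standard residues: ", paste(unique(bad), collapse = ", "))
  invisible(seq)
}
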