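# Synthetic genome assemblies with planted epilancin-like clusters.
#
# The generator plants (possibly diverged, possibly broken) copies of the
# bundled reference cluster into random flanking sequence and returns an
# exact truth table, so the mining and phylogeny stages can be scored against
# planted ground truth. Anomalies mirror the cluster variants observed in
# public staphylococcal assemblies: pseudogenes from frameshifts, gene
# truncations, genes or whole clusters in reverse orientation, and gene
# losses (including loss of the precursor gene, which downstream mining must
# reject).

#' Specify a synthetic cluster to plant
#'
#' @param genes character vector of cluster genes to include, a subset of the
#'   nine reference genes, in the order they are planted.
#' @param divergence per-gene fraction of residues substituted, either a
#'   single value or a named vector over `genes`; each in `[0, 1]`.
#' @param anomalies list of anomaly descriptors, each created by
#'   [anomaly_frameshift()], [anomaly_truncate()], [anomaly_reverse()],
#'   [anomaly_delete()] or [anomaly_reverse_cluster()].
#' @param flank_length nucleotides of i.i.d. uniform ACGT sequence on each
#'   side of the cluster.
#' @param spacer_length nucleotides between adjacent genes (default 50).
#' @param seed integer seed; identical specs and seeds give byte-identical
#'   assemblies.
#' @return a `cluster_spec` list.
#' @export
cluster_spec <- function(genes = ELA_GENES, divergence = 0, anomalies = list(),
                         flank_length = 1000L, spacer_length = 50L,
                         seed = 1L) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("gene names must be unique")
  if (!all(genes %in% ELA_GENES))
    stop("unknown genes: ", paste(setdiff(genes, ELA_GENES), collapse = ", "))
  if (length(divergence) == 1L && is.null(names(divergence)))
    divergence <- setNames(rep(divergence, length(genes)), genes)
  if (!all(genes %in% names(divergence)))
    stop("divergence must cover every gene")
  divergence <- divergence[genes]
  if (any(divergence < 0 | divergence > 1)) stop("divergence must be in [0, 1]")
  if (flank_length < 0) stop("flank_length must be >= 0")
  for (an in anomalies) {
    if (!is.null(an$gene) && !(an$gene %in% genes))
      stop("anomaly references absent gene: ", an$gene)
  }
  deleted <- vapply(anomalies, function(a) if (a$type == "delete") a$gene else NA_character_,
                    character(1))
  for (an in anomalies) {
    if (an$type %in% c("frameshift", "truncate", "reverse") &&
        an$gene %in% deleted)
      stop("anomaly on a deleted gene: ", an$gene)
  }
  structure(list(genes = genes, divergence = divergence, anomalies = anomalies,
                 flank_length = as.integer(flank_length),
                 spacer_length = as.integer(spacer_length),
                 seed = as.integer(seed)),
            class = "cluster_spec")
}

#' @rdname cluster_spec
#' @param gene gene name the anomaly applies to.
#' @param codon 1-based codon index at which the frameshift is inserted.
#' @export
anomaly_frameshift <- function(gene, codon) list(type = "frameshift", gene = gene, codon = as.integer(codon))
#' @rdname cluster_spec
#' @param fraction fraction of the protein retained before the stop.
#' @export
anomaly_truncate <- function(gene, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  list(type = "truncate", gene = gene, fraction = fraction)
}
#' @rdname cluster_spec
#' @export
anomaly_reverse <- function(gene) list(type = "reverse", gene = gene)
#' @rdname cluster_spec
#' @export
anomaly_delete <- function(gene) list(type = "delete", gene = gene)
#' @rdname cluster_spec
#' @export
anomaly_reverse_cluster <- function() list(type = "reverse_cluster", gene = NULL)

#' Substitute a fraction of residues in a protein
#'
#' `round(divergence * nchar)` positions are drawn without replacement and
#' each is replaced by a residue drawn uniformly from the 19 alternatives, so
#' the realized identity to the input is `1 - divergence` up to rounding.
#'
#' @param seq amino-acid string.
#' @param divergence fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return mutated amino-acid string.
#' @export
mutate_protein <- function(seq, divergence, seed = 1L) {
  assert_protein(seq, "seq")
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  aa <- strsplit(seq, "")[[1]]
  n_sub <- round(divergence * length(aa))
  if (n_sub == 0L) return(seq)
  with_seed(seed, {
    pos <- sample(length(aa), n_sub)
    for (p in pos) {
      alt <- setdiff(AA20, aa[p])
      aa[p] <- alt[sample.int(length(alt), 1L)]
    }
  })
  paste(aa, collapse = "")
}

# Insert a 1-nt frameshift after codon `codon`; picks the inserted base (in
# fixed A,C,G,T order) so that a premature stop appears downstream in the
# shifted frame, mimicking a pseudogene.
.frameshift_cds <- function(cds, codon) {
  cut <- 3L * (codon - 1L)
  if (cut >= nchar(cds)) stop("frameshift codon beyond gene end")
  for (base in c("A", "C", "G", "T")) {
    shifted <- paste0(substr(cds, 1, cut), base,
                      substr(cds, cut + 1L, nchar(cds)))
    tr <- translate_dna(shifted, to_stop = TRUE)
    if (nchar(tr) * 3L < nchar(shifted) - 3L) return(shifted)
  }
  shifted # no early stop found (vanishingly unlikely); still a frameshift
}

#' Generate a synthetic assembly with a planted cluster
#'
#' @param spec a [cluster_spec()].
#' @return a list with `assembly` (named character vector of contigs) and
#'   `truth` (data.frame: gene, present, contig, start, end, strand, identity,
#'   anomaly; coordinates 0-based half-open on the forward strand) plus
#'   `proteins` (the planted, post-anomaly proteins) and `cds`.
#' @export
generate_assembly <- function(spec) {
  stopifnot(inherits(spec, "cluster_spec"))
  ref <- ela_reference()
  anomaly_of <- function(g, type) {
    Filter(function(a) identical(a$gene, g) && a$type == type, spec$anomalies)
  }
  rev_cluster <- any(vapply(spec$anomalies, function(a) a$type == "reverse_cluster", logical(1)))

  planted <- list() # per retained gene: protein, cds, strand, anomaly, identity
  for (g in spec$genes) {
    if (length(anomaly_of(g, "delete"))) next
    prot <- mutate_protein(ref$proteins[[g]], spec$divergence[[g]],
                           seed = spec$seed + match(g, ELA_GENES))
    # keep the initiator Met so the planted ORF start is exact
    prot <- paste0("M", substr(prot, 2, nchar(prot)))
    ident <- mean(strsplit(prot, "")[[1]] == strsplit(ref$proteins[[g]], "")[[1]])
    anomaly <- ""
    tr <- anomaly_of(g, "truncate")
    if (length(tr)) {
      keep <- max(1L, floor(tr[[1]]$fraction * nchar(prot)))
      prot <- substr(prot, 1, keep)
      anomaly <- "truncated"
    }
    cds <- back_translate(prot)
    fs <- anomaly_of(g, "frameshift")
    if (length(fs)) {
      cds <- .frameshift_cds(cds, fs[[1]]$codon)
      anomaly <- "pseudogene"
    }
    strand <- if (length(anomaly_of(g, "reverse"))) "-" else "+"
    if (strand == "-") anomaly <- if (nzchar(anomaly)) paste0(anomaly, ";reversed") else "reversed"
    planted[[g]] <- list(protein = prot, cds = cds, strand = strand,
                         anomaly = anomaly, identity = ident)
  }

  spacer_pool <- with_seed(spec$seed * 7L + 11L, {
    paste(sample(c("A", "C", "G", "T"),
                 spec$spacer_length * (length(planted) + 1L) + 2L * spec$flank_length,
                 replace = TRUE), collapse = "")
  })
  take <- local({
    off <- 0L
    function(n) {
      s <- substr(spacer_pool, off + 1L, off + n)
      off <<- off + n
      s
    }
  })

  left <- take(spec$flank_length)
  pieces <- character(0)
  coords <- list()
  pos <- nchar(left)
  first <- TRUE
  for (g in names(planted)) {
    if (!first) {
      sp <- take(spec$spacer_length)
      pieces <- c(pieces, sp); pos <- pos + nchar(sp)
    }
    first <- FALSE
    p <- planted[[g]]
    seq_fwd <- if (p$strand == "+") p$cds else revcomp(p$cds)
    coords[[g]] <- c(start = pos, end = pos + nchar(seq_fwd))
    pieces <- c(pieces, seq_fwd)
    pos <- pos + nchar(seq_fwd)
  }
  cluster_block <- paste(pieces, collapse = "")
  cluster_start <- nchar(left)
  if (rev_cluster) {
    cluster_block <- revcomp(cluster_block)
    blk <- nchar(cluster_block)
    coords <- lapply(coords, function(co) {
      c(start = cluster_start + (blk - (co[["end"]] - cluster_start)),
        end = cluster_start + (blk - (co[["start"]] - cluster_start)))
    })
  }
  right <- take(spec$flank_length)
  contig <- paste0(left, cluster_block, right)

  truth <- do.call(rbind, lapply(ELA_GENES, function(g) {
    if (!is.null(planted[[g]])) {
      p <- planted[[g]]
      strand <- p$strand
      if (rev_cluster) strand <- if (strand == "+") "-" else "+"
      anomaly <- p$anomaly
      if (rev_cluster) anomaly <- if (nzchar(anomaly)) paste0(anomaly, ";reversed_cluster") else "reversed_cluster"
      data.frame(gene = g, present = TRUE, contig = "contig_1",
                 start = unname(coords[[g]][["start"]]),
                 end = unname(coords[[g]][["end"]]),
                 strand = strand, identity = p$identity, anomaly = anomaly,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = g, present = FALSE, contig = NA_character_,
                 start = NA_integer_, end = NA_integer_,
                 strand = NA_character_, identity = NA_real_,
                 anomaly = if (g %in% spec$genes) "missing" else "not_in_spec",
                 stringsAsFactors = FALSE)
    }
  }))
  stopifnot(all(is.na(truth$start) | (truth$start < truth$end & truth$end <= nchar(contig))))

  list(assembly = c(contig_1 = contig), truth = truth,
       proteins = vapply(planted, `[[`, character(1), "protein"),
       cds = vapply(planted, `[[`, character(1), "cds"))
}

#' Write an assembly and its truth table to disk
#'
#' @param asm result of [generate_assembly()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named vector of the two file paths.
#' @export
write_assembly <- function(asm, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fna"))
  tr <- file.path(dir, paste0(prefix, "_truth.csv"))
  write_fasta(asm$assembly, fa)
  write.csv(asm$truth, tr, row.names = FALSE)
  c(fasta = fa, truth = tr)
}
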