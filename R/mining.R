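# Epilancin cluster detection: homology screen + coverage/completeness
# filters + anomaly annotation + similarity typing.
#
# Filter conventions follow the published screen: homologs require >70%
# reference coverage; a candidate cluster is emitted only if strictly more
# than 50% of the nine reference genes are present (i.e. at least five) AND
# the precursor gene elaA is among them. Pseudogenes (ORFs interrupted by a
# premature stop) fail the coverage filter and are rescued by a second-tier
# scan (coverage in [0.25, 0.70]); they count toward completeness but carry a
# `pseudogene` anomaly flag. Truncation is called for passing hits with
# coverage in (0.70, 0.85] -- a repo convention, the source screen states
# "truncated" only qualitatively.

#' Score assembly ORFs against the reference cluster proteins
#'
#' @param orfs data.frame from [find_orfs()].
#' @param reference named character vector of reference proteins (defaults to
#'   the bundled cluster).
#' @param min_identity minimum alignment identity to keep a hit.
#' @param partial_coverage lower coverage bound for second-tier (pseudogene
#'   candidate) hits.
#' @param partial_identity stricter identity floor for second-tier hits
#'   (short local alignments inflate identity, so sub-threshold-coverage
#'   fragments must clear a higher bar).
#' @return data.frame of best hit per ORF: orf row index, gene, identity,
#'   coverage, score, tier ("pass" for coverage > 0.70, "partial" otherwise),
#'   plus the ORF coordinates.
#' @export
scan_homology <- function(orfs, reference = ela_reference()$proteins,
                          min_identity = 0.35, partial_coverage = 0.25,
                          partial_identity = 0.45) {
  hits <- list()
  for (i in seq_len(nrow(orfs))) {
    prot <- orfs$protein[i]
    best <- NULL
    for (g in names(reference)) {
      ref <- reference[[g]]
      if (nchar(prot) < partial_coverage * nchar(ref)) next
      a <- align_proteins(prot, ref)
      if (is.null(best) || a$score > best$score) {
        best <- a; best$gene <- g
      }
    }
    if (is.null(best)) next
    if (best$identity < min_identity) next
    if (best$coverage <= partial_coverage) next
    if (best$coverage <= 0.70 && best$identity < partial_identity) next
    # refine the ORF span to the gene: extrapolate the alignment to
    # reference position 1 and include the stop codon (0-based half-open,
    # forward strand), clipped to the ORF
    s <- orfs$start[i]; e <- orfs$end[i]
    ref_len <- nchar(reference[[best$gene]])
    q1 <- best$q_start - (best$r_start - 1L)
    if (orfs$strand[i] == "+") {
      gs <- max(s, s + 3L * (q1 - 1L))
      ge <- min(e, gs + 3L * (ref_len + 1L))
    } else {
      ge <- min(e, e - 3L * (q1 - 1L))
      gs <- max(s, ge - 3L * (ref_len + 1L))
    }
    hits[[length(hits) + 1L]] <- data.frame(
      orf = i, gene = best$gene, identity = best$identity,
      coverage = best$coverage, score = best$score,
      tier = if (best$coverage > 0.70) "pass" else "partial",
      contig = orfs$contig[i], start = gs, end = ge,
      strand = orfs$strand[i], length_aa = orfs$length_aa[i],
      stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(orf = integer(), gene = character(), identity = numeric(),
                      coverage = numeric(), score = numeric(), tier = character(),
                      contig = character(), start = integer(), end = integer(),
                      strand = character(), length_aa = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Group homology hits into cluster calls
#'
#' Hits on one contig whose spans lie within `window` nucleotides of each
#' other are grouped. A group becomes a cluster call iff at least five of the
#' nine reference genes are present (strict > 50% completeness) and elaA is
#' present. Anomalies: premature internal stop relative to the reference ->
#' `pseudogene`; passing coverage in (0.70, 0.85] -> `truncated`; hit on the
#' minority strand -> `reversed`; majority strand "-" -> `reversed_cluster`;
#' reference genes without a hit -> `missing`.
#'
#' @param hits data.frame from [scan_homology()]; passing hits must have
#'   coverage > 0.70.
#' @param window maximum nucleotide gap between adjacent member hits.
#' @param min_completeness completeness threshold (strict inequality).
#' @param truncation_coverage upper coverage bound for the `truncated` call.
#' @return list of cluster calls; each is a list with contig, span, genes
#'   (per-gene data.frame), completeness, anomalies (character vector),
#'   strand.
#' @export
call_clusters <- function(hits, window = 5000L, min_completeness = 0.5,
                          truncation_coverage = 0.85) {
  if (!nrow(hits)) return(list())
  calls <- list()
  for (ctg in unique(hits$contig)) {
    h <- hits[hits$contig == ctg, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(h$start[-1] - h$end[-nrow(h)] > window)))
    for (gi in unique(grp)) {
      hg <- h[grp == gi, , drop = FALSE]
      # genes hit by several ORF fragments are broken in-frame: a premature
      # internal stop splits the gene into pieces (pseudogene signature)
      fragmented <- names(which(table(hg$gene) > 1L))
      # one best hit per reference gene (reciprocal filter within the group)
      hg <- hg[order(hg$gene, -hg$score), , drop = FALSE]
      hg <- hg[!duplicated(hg$gene), , drop = FALSE]
      pass <- hg[hg$tier == "pass", , drop = FALSE]
      partial <- hg[hg$tier == "partial", , drop = FALSE]
      ref_len <- nchar(ela_reference()$proteins)
      # pseudogene rescue: partial hit whose ORF stops well before the
      # reference end (premature internal stop)
      pseudo <- partial[partial$length_aa < 0.9 * ref_len[partial$gene], , drop = FALSE]
      present <- rbind(pass, pseudo)
      if (!nrow(present)) next
      completeness <- nrow(present) / length(ELA_GENES)
      if (!(completeness > min_completeness) || !("elaA" %in% present$gene)) next
      strand_major <- if (sum(present$strand == "-") > nrow(present) / 2) "-" else "+"
      anomalies <- character(0)
      per_gene <- present[order(match(present$gene, ELA_GENES)), , drop = FALSE]
      for (k in seq_len(nrow(per_gene))) {
        g <- per_gene$gene[k]
        if (per_gene$tier[k] == "partial" || g %in% fragmented)
          anomalies <- c(anomalies, paste0("pseudogene(", g, ")"))
        else if (per_gene$coverage[k] <= truncation_coverage)
          anomalies <- c(anomalies, paste0("truncated(", g, ")"))
        if (per_gene$strand[k] != strand_major)
          anomalies <- c(anomalies, paste0("reversed(", g, ")"))
      }
      if (strand_major == "-") anomalies <- c(anomalies, "reversed_cluster")
      for (g in setdiff(ELA_GENES, per_gene$gene))
        anomalies <- c(anomalies, paste0("missing(", g, ")"))
      calls[[length(calls) + 1L]] <- list(
        contig = ctg, span = c(min(per_gene$start), max(per_gene$end)),
        genes = per_gene, completeness = completeness,
        anomalies = anomalies, strand = strand_major)
    }
  }
  calls
}

#' Type a cluster call against a catalogue of known clusters
#'
#' The call's member proteins are aligned against each catalogue entry's
#' proteins over shared genes; the label of the entry maximizing mean
#' per-gene identity is returned, or `"novel"` when that mean falls below
#' `min_identity`. Ties break by catalogue order.
#'
#' @param call one element of [call_clusters()] output.
#' @param proteins named character vector of the call's member proteins (the
#'   mined ORF translations, named by gene).
#' @param catalogue named list; each entry a named character vector of
#'   per-gene proteins.
#' @param min_identity mean-identity threshold for a known label.
#' @return list with `label`, `nearest` (best entry), `mean_identity`.
#' @export
classify_cluster <- function(call, proteins, catalogue, min_identity = 0.95) {
  stopifnot(length(catalogue) >= 1L)
  shared_any <- FALSE
  means <- vapply(catalogue, function(entry) {
    shared <- intersect(names(proteins), names(entry))
    if (!length(shared)) return(NA_real_)
    shared_any <<- TRUE
    mean(vapply(shared, function(g) align_proteins(proteins[[g]], entry[[g]])$identity,
                numeric(1)))
  }, numeric(1))
  if (!shared_any || all(is.na(means))) stop("cluster call has no scored gene")
  best <- which.max(means) # first maximum: catalogue-order tie-break
  list(label = if (means[best] >= min_identity) names(catalogue)[best] else "novel",
       nearest = names(catalogue)[best], mean_identity = unname(means[best]))
}

#' Mine an assembly for epilancin-like clusters
#'
#' Convenience pipeline: [find_orfs()] -> [scan_homology()] ->
#' [call_clusters()]; attaches member ORF translations to each call.
#'
#' @inheritParams find_orfs
#' @inheritParams scan_homology
#' @inheritParams call_clusters
#' @return list of cluster calls, each augmented with `proteins`.
#' @export
mine_assembly <- function(assembly, reference = ela_reference()$proteins,
                          min_orf_len = 50L, min_identity = 0.35,
                          window = 5000L, min_completeness = 0.5) {
  orfs <- find_orfs(assembly, min_orf_len = min_orf_len)
  hits <- scan_homology(orfs, reference, min_identity = min_identity)
  calls <- call_clusters(hits, window = window, min_completeness = min_completeness)
  lapply(calls, function(cl) {
    cl$proteins <- setNames(orfs$protein[cl$genes$orf], cl$genes$gene)
    cl
  })
}

#' Export cluster calls as a flat table
#'
#' @param calls list from [mine_assembly()] or [call_clusters()].
#' @return data.frame with one row per member gene (1-based inclusive
#'   coordinates for reporting).
#' @export
cluster_call_table <- function(calls) {
  if (!length(calls))
    return(data.frame(cluster = integer(), contig = character(), gene = character(),
                      start = integer(), end = integer(), strand = character(),
                      identity = numeric(), coverage = numeric(),
                      completeness = numeric(), anomalies = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(calls), function(i) {
    cl <- calls[[i]]
    data.frame(cluster = i, contig = cl$contig, gene = cl$genes$gene,
               start = cl$genes$start + 1L, end = cl$genes$end,
               strand = cl$genes$strand, identity = cl$genes$identity,
               coverage = cl$genes$coverage, completeness = cl$completeness,
               anomalies = paste(cl$anomalies, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
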