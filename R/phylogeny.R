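# Concatenated-gene cluster phylogeny: concatenation with gene omission and
# label exclusion, an own progressive multiple aligner (k-mer distance guide
# tree + profile-profile merging), p-distances, and an own neighbor-joining
# implementation with deterministic tie-breaking. Maximum-likelihood
# inference is deliberately not used: the claim under test is the
# concatenation/omission logic and topology recovery on planted data.

#' Concatenate cluster gene coding sequences
#'
#' Genes follow the reference order; `omit` genes are dropped from every
#' record (e.g. elaO, absent from some clusters), and records whose label is
#' in `exclude` are removed entirely (e.g. a compositionally divergent
#' cluster). Genes missing from a retained record are filled with an all-gap
#' slot of the reference CDS length so columns stay positionally comparable.
#'
#' @param clusters named list; each element a named character vector of
#'   per-gene coding sequences (names are cluster labels).
#' @param omit character vector of gene names to drop.
#' @param exclude character vector of cluster labels to remove.
#' @return list of records: `label`, `sequence`, `gene_order`.
#' @export
concatenate_clusters <- function(clusters, omit = "elaO", exclude = character()) {
  if (anyDuplicated(names(clusters))) stop("duplicate cluster labels")
  ref <- ela_reference()
  order_use <- setdiff(ref$genes, omit)
  keep <- setdiff(names(clusters), exclude)
  lapply(keep, function(lab) {
    cds <- clusters[[lab]]
    parts <- vapply(order_use, function(g) {
      if (g %in% names(cds)) cds[[g]]
      else strrep("-", nchar(ref$cds[[g]]))
    }, character(1))
    list(label = lab, sequence = paste(parts, collapse = ""),
         gene_order = order_use)
  })
}

# k-mer (default 6) distance between two DNA strings: 1 - shared/min kmers
kmer_distance <- function(a, b, k = 6L) {
  km <- function(s) {
    s <- gsub("-", "", s)
    if (nchar(s) < k) return(character(0))
    substring(s, 1:(nchar(s) - k + 1L), k:nchar(s))
  }
  ka <- km(a); kb <- km(b)
  if (!length(ka) || !length(kb)) return(1)
  ta <- table(ka); tb <- table(kb)
  common <- intersect(names(ta), names(tb))
  shared <- sum(pmin(ta[common], tb[common]))
  1 - shared / min(length(ka), length(kb))
}

#' Progressive multiple sequence alignment
#'
#' Pairwise k-mer distances give a UPGMA guide tree; profiles are merged
#' bottom-up with a global profile-profile aligner (match 1, mismatch -1,
#' gap -2, linear). Removing the gaps of any output row recovers the input.
#'
#' @param seqs named character vector of DNA sequences (>= 2).
#' @param k k-mer size for the guide distances.
#' @return named character vector of equal-length aligned rows.
#' @export
align_msa <- function(seqs, k = 6L) {
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  # alignment state per active node: character matrix, rows = sequences
  nodes <- lapply(seq_len(n), function(i) {
    m <- matrix(strsplit(seqs[[i]], "")[[1]], nrow = 1)
    rownames(m) <- names(seqs)[i]
    m
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- kmer_distance(seqs[[i]], seqs[[j]], k)
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- c(idx[1], idx[2]); bd <- Inf
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a) next
      if (D[idx[a], idx[b]] < bd) { bd <- D[idx[a], idx[b]]; best <- c(idx[a], idx[b]) }
    }
    i <- best[1]; j <- best[2]
    merged <- merge_profiles(nodes[[i]], nodes[[j]])
    # UPGMA update of distances
    for (m in which(active)) {
      if (m == i || m == j) next
      D[i, m] <- D[m, i] <- (sizes[i] * D[i, m] + sizes[j] * D[j, m]) /
        (sizes[i] + sizes[j])
    }
    nodes[[i]] <- merged
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  out <- nodes[[which(active)]]
  res <- apply(out, 1, paste, collapse = "")
  res[names(seqs)] # restore input order
}

merge_profiles <- function(A, B) {
  prof <- function(M) {
    sym <- c("A", "C", "G", "T", "-")
    p <- vapply(seq_len(ncol(M)), function(j) {
      col <- M[, j]
      tabulate(match(col, sym), 5L) / length(col)
    }, numeric(5))
    matrix(p, nrow = 5)
  }
  path <- cpp_profile_align(prof(A), prof(B), 1, -1, -2)
  L <- ncol(path)
  out <- matrix("-", nrow = nrow(A) + nrow(B), ncol = L)
  rownames(out) <- c(rownames(A), rownames(B))
  ia <- path[1, ]; ib <- path[2, ]
  out[seq_len(nrow(A)), ia > 0] <- A[, ia[ia > 0], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), ib > 0] <- B[, ib[ib > 0], drop = FALSE]
  out
}

#' Pairwise p-distances from a multiple alignment
#'
#' Proportion of differing sites among columns where both rows are ungapped.
#'
#' @param msa named character vector of aligned rows.
#' @return symmetric distance matrix.
#' @export
p_distance <- function(msa) {
  n <- length(msa)
  M <- do.call(rbind, strsplit(msa, ""))
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- M[i, ] != "-" & M[j, ] != "-"
    D[i, j] <- D[j, i] <- if (!any(ok)) 0 else mean(M[i, ok] != M[j, ok])
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (Saitou-Nei, Studier-Keppler Q-criterion) with
#' deterministic tie-breaking: at equal Q the pair with the lowest row index,
#' then lowest column index, is joined. Negative branch-length estimates are
#' clamped to zero and flagged. On additive distance matrices NJ is exact.
#'
#' @param D symmetric distance matrix with zero diagonal, >= 3 taxa.
#' @return list with `newick` (string), `phylo` (an [ape::read.tree()]
#'   object), `clamped` (number of negative branch lengths clamped).
#' @export
nj_tree <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  nodes <- as.list(labels) # newick fragments
  lens <- rep(NA_real_, n)
  D <- unname(D)
  clamped <- 0L
  fmt <- function(x) sprintf("%.10g", x)
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- c(1L, 2L); bq <- Inf
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (Q[i, j] < bq - 1e-12) { bq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { clamped <- clamped + 1L; li <- 0 }
    if (lj < 0) { clamped <- clamped + 1L; lj <- 0 }
    newnode <- paste0("(", nodes[[i]], ":", fmt(li), ",",
                      nodes[[j]], ":", fmt(lj), ")")
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- matrix(0, n - 1, n - 1)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
    D2[n - 1, seq_along(keep)] <- D2[seq_along(keep), n - 1] <- dnew[keep]
    D <- D2
    nodes <- c(nodes[keep], newnode)
    n <- n - 1L
  }
  # final three nodes: closed-form branch lengths
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (v in c("la", "lb", "lc")) {
    if (get(v) < 0) { clamped <- clamped + 1L; assign(v, 0) }
  }
  newick <- paste0("(", nodes[[1]], ":", fmt(la), ",", nodes[[2]], ":", fmt(lb),
                   ",", nodes[[3]], ":", fmt(lc), ");")
  list(newick = newick, phylo = ape::read.tree(text = newick), clamped = clamped)
}

#' Simulate a horizontal-transfer scenario for topology recovery
#'
#' Two cluster lineages (X and Y) diverge from the reference ancestor at
#' `base_divergence`; each lineage is then sampled into `members` clusters at
#' `member_divergence`, and the members are assigned to interleaved host
#' labels. Under horizontal transfer the cluster tree should group members by
#' cluster lineage, not by host order, so recovery is measured as monophyly
#' of each lineage's members in the unrooted tree. The default problem size
#' (three short genes, six taxa) keeps one replicate well under a second so
#' recovery fractions can be estimated over many seeds.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param genes genes to simulate (default the three shortest cluster genes).
#' @param base_divergence per-lineage divergence from the ancestor.
#' @param member_divergence within-lineage divergence per member.
#' @param members clusters sampled per lineage.
#' @return list: `clusters` (named per-gene CDS vectors, labels
#'   `host<letter>_<lineage>`), `lineages` (named character vector mapping
#'   label to lineage), `genes`, `omit` (the reference genes not simulated,
#'   to pass to [cluster_phylogeny()]).
#' @export
transfer_scenario <- function(seed, genes = c("elaA", "elaI1", "elaI3"),
                              base_divergence = 0.2, member_divergence = 0.02,
                              members = 3L) {
  ref <- ela_reference()
  stopifnot(all(genes %in% ref$genes), members >= 2L)
  anc <- lapply(setNames(genes, genes), function(g) ref$proteins[[g]])
  lin <- list(
    X = lapply(anc, mutate_protein, divergence = base_divergence,
               seed = seed * 13L + 1L),
    Y = lapply(anc, mutate_protein, divergence = base_divergence,
               seed = seed * 13L + 2L))
  labels <- character(0); lineage_of <- character(0); clusters <- list()
  for (k in seq_len(2L * members)) {
    ln <- if (k %% 2L == 1L) "X" else "Y" # interleaved host order
    prots <- lapply(seq_along(genes), function(i)
      mutate_protein(lin[[ln]][[i]], member_divergence,
                     seed = seed * 101L + k * 7L + i))
    lab <- paste0("host", LETTERS[k], "_", ln)
    clusters[[lab]] <- setNames(vapply(prots, back_translate, character(1)), genes)
    lineage_of[lab] <- ln
  }
  list(clusters = clusters, lineages = lineage_of, genes = genes,
       omit = setdiff(ref$genes, genes))
}

#' Lineage-monophyly recovery of a transfer scenario
#'
#' Builds the tree with [cluster_phylogeny()] and checks that each lineage's
#' members form a clade of the unrooted topology.
#'
#' @param scenario a [transfer_scenario()] result.
#' @return TRUE iff every lineage is monophyletic.
#' @export
transfer_recovered <- function(scenario) {
  tr <- cluster_phylogeny(scenario$clusters, omit = scenario$omit)
  phy <- ape::unroot(tr$phylo)
  all(vapply(unique(scenario$lineages), function(ln)
    ape::is.monophyletic(phy, names(scenario$lineages)[scenario$lineages == ln]),
    logical(1)))
}

#' Build the cluster phylogeny from per-cluster gene sequences
#'
#' Concatenation (with omission/exclusion) -> progressive alignment ->
#' p-distance -> neighbor joining.
#'
#' @inheritParams concatenate_clusters
#' @return as [nj_tree()], plus `msa` and `distances`.
#' @export
cluster_phylogeny <- function(clusters, omit = "elaO", exclude = character()) {
  recs <- concatenate_clusters(clusters, omit = omit, exclude = exclude)
  seqs <- setNames(vapply(recs, `[[`, character(1), "sequence"),
                   vapply(recs, `[[`, character(1), "label"))
  msa <- align_msa(seqs)
  D <- p_distance(msa)
  tr <- nj_tree(D)
  tr$msa <- msa
  tr$distances <- D
  tr
}
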