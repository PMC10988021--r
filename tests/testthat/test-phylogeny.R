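test_that("concatenation follows reference order, omits elaO, pads missing genes", {
  ref <- ela_reference()
  full <- setNames(ref$cds, ref$genes)
  partial <- full[c("elaA", "elaP", "elaB")]
  recs <- concatenate_clusters(list(full = full, partial = partial))
  expect_identical(recs[[1]]$gene_order, setdiff(ref$genes, "elaO"))
  expect_identical(nchar(recs[[1]]$sequence), nchar(recs[[2]]$sequence))
  # elaO is dropped entirely
  expect_identical(nchar(recs[[1]]$sequence),
                   sum(nchar(ref$cds[setdiff(ref$genes, "elaO")])))
  # missing genes come back as all-gap slots of the reference length
  gapless <- gsub("-", "", recs[[2]]$sequence)
  expect_identical(nchar(gapless), sum(nchar(ref$cds[c("elaA", "elaP", "elaB")])))
  expect_error(concatenate_clusters(list(a = full, a = full)), "duplicate")
})

test_that("excluded labels are removed before alignment", {
  ref <- ela_reference()
  full <- setNames(ref$cds, ref$genes)
  recs <- concatenate_clusters(list(keep = full, drop = full), exclude = "drop")
  expect_identical(vapply(recs, `[[`, character(1), "label"), "keep")
})

test_that("degapping any alignment row recovers its input sequence", {
  seqs <- c(a = "ACGTACGTACGTAA", b = "ACGTACGGTACGTAA", c = "ACGTACGTACGAA")
  msa <- align_msa(seqs, k = 4L)
  expect_identical(length(unique(nchar(msa))), 1L)
  for (nm in names(seqs))
    expect_identical(gsub("-", "", msa[[nm]]), unname(seqs[[nm]]))
})

test_that("pairwise MSA scores equal the linear-gap DP oracle", {
  set.seed(77)
  for (rep in 1:6) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(10:30, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(10:30, 1), replace = TRUE),
               collapse = "")
    msa <- align_msa(c(x = a, y = b), k = 4L)
    cols <- cbind(strsplit(msa[["x"]], "")[[1]], strsplit(msa[["y"]], "")[[1]])
    realized <- sum(ifelse(cols[, 1] == "-" | cols[, 2] == "-", -2,
                           ifelse(cols[, 1] == cols[, 2], 1, -1)))
    expect_equal(realized, oracle_nw_score(a, b), info = rep)
  }
})

test_that("p-distance counts differences over mutually ungapped sites", {
  msa <- c(a = "ACGT--AC", b = "ACTTG-AC", c = "--GTGGAC")
  D <- p_distance(msa)
  expect_equal(D["a", "b"], 1 / 6) # 6 shared ungapped sites, 1 difference
  expect_equal(D["a", "c"], 0 / 4)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
})

test_that("three-taxon neighbor joining solves the closed form exactly", {
  D <- matrix(c(0, 3, 5,
                3, 0, 6,
                5, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  ph <- tr$phylo
  bl <- setNames(ph$edge.length, ph$tip.label[ph$edge[, 2]])
  expect_equal(unname(bl["A"]), (3 + 5 - 6) / 2)
  expect_equal(unname(bl["B"]), (3 + 6 - 5) / 2)
  expect_equal(unname(bl["C"]), (5 + 6 - 3) / 2)
  expect_identical(tr$clamped, 0L)
})

test_that("additive distances are recovered exactly for 4 and 5 taxa", {
  # build additive matrices from random trees and check patristic closure
  for (n in 4:5) for (s in 1:3) {
    phy <- with_seed(n * 10 + s, ape::rtree(n, br = function(k) runif(k, 0.1, 1)))
    D <- ape::cophenetic.phylo(phy)
    D <- D[sort(rownames(D)), sort(colnames(D))]
    tr <- nj_tree(D)
    D2 <- ape::cophenetic.phylo(tr$phylo)
    expect_equal(D2[rownames(D), colnames(D)], D, tolerance = 1e-9)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(phy), tr$phylo)), 0)
  }
})

test_that("negative branch estimates are clamped and counted", {
  D <- matrix(c(0, 1, 10, 10,
                1, 0, 10, 10,
                10, 10, 0, 1,
                10, 10, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  # violate additivity so an internal estimate goes negative
  D["a", "c"] <- D["c", "a"] <- 0.5
  tr <- nj_tree(D)
  expect_gte(tr$clamped, 1L)
  expect_true(all(tr$phylo$edge.length >= 0))
})

test_that("distance matrices must be symmetric with at least three taxa", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(nj_tree(D), "at least 3")
  D3 <- matrix(c(0, 1, 2,
                 1.5, 0, 1,
                 2, 1, 0), 3, 3)
  expect_error(nj_tree(D3), "symmetric")
})

test_that("transfer scenarios group clusters by lineage, not by host order", {
  sc <- transfer_scenario(1L)
  expect_identical(sort(unique(unname(sc$lineages))), c("X", "Y"))
  expect_true(transfer_recovered(sc))
  # host labels alternate lineages, so host-order grouping would fail
  expect_identical(unname(sc$lineages[1:4]), c("X", "Y", "X", "Y"))
})
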