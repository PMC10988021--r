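test_that("identical specs and seeds give byte-identical assemblies", {
  spec <- cluster_spec(divergence = 0.1, seed = 77L)
  a1 <- generate_assembly(spec)
  a2 <- generate_assembly(spec)
  expect_identical(a1$assembly, a2$assembly)
  expect_identical(a1$truth, a2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- write_assembly(a1, d1)
  f2 <- write_assembly(a2, d2)
  expect_identical(readBin(f1[["fasta"]], "raw", file.size(f1[["fasta"]])),
                   readBin(f2[["fasta"]], "raw", file.size(f2[["fasta"]])))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("different seeds change the assembly", {
  a1 <- generate_assembly(cluster_spec(seed = 1L))
  a2 <- generate_assembly(cluster_spec(seed = 2L))
  expect_false(identical(a1$assembly, a2$assembly))
})

test_that("planted divergence is realized as 1 - identity up to rounding", {
  for (d in c(0, 0.1, 0.3)) {
    asm <- generate_assembly(cluster_spec(divergence = d, seed = 5L))
    ref <- ela_reference()
    for (g in ELA_GENES) {
      n <- nchar(ref$proteins[[g]])
      planted_id <- asm$truth$identity[asm$truth$gene == g]
      # the initiator Met is pinned, so at most one substituted position is
      # restored relative to the nominal count
      expect_gte(planted_id, 1 - round(d * n) / n)
      expect_lte(planted_id, 1 - (round(d * n) - 1) / n + 1e-12)
    }
  }
})

test_that("planted coordinates slice the contig to the planted CDS", {
  asm <- generate_assembly(cluster_spec(divergence = 0.2, seed = 9L))
  ctg <- asm$assembly[["contig_1"]]
  for (g in ELA_GENES) {
    row <- asm$truth[asm$truth$gene == g, ]
    sub <- substr(ctg, row$start + 1L, row$end) # 0-based half-open
    expect_identical(sub, asm$cds[[g]])
    expect_identical(translate_dna(sub), asm$proteins[[g]])
  }
})

test_that("reverse-cluster coordinates track the flipped gene copies", {
  asm <- generate_assembly(cluster_spec(
    anomalies = list(anomaly_reverse_cluster()), seed = 3L))
  ctg <- asm$assembly[["contig_1"]]
  for (g in ELA_GENES) {
    row <- asm$truth[asm$truth$gene == g, ]
    expect_identical(row$strand, "-")
    expect_match(row$anomaly, "reversed_cluster")
    sub <- substr(ctg, row$start + 1L, row$end)
    expect_identical(revcomp(sub), asm$cds[[g]])
  }
})

test_that("a frameshift inserts one base and creates a premature stop", {
  asm0 <- generate_assembly(cluster_spec(seed = 4L))
  asm <- generate_assembly(cluster_spec(
    anomalies = list(anomaly_frameshift("elaP", 40L)), seed = 4L))
  row <- asm$truth[asm$truth$gene == "elaP", ]
  expect_identical(row$anomaly, "pseudogene")
  expect_identical(nchar(asm$cds[["elaP"]]), nchar(asm0$cds[["elaP"]]) + 1L)
  tr <- translate_dna(asm$cds[["elaP"]], to_stop = TRUE)
  expect_lt(nchar(tr) * 3L, nchar(asm$cds[["elaP"]]) - 3L)
})

test_that("truncation keeps the requested fraction of residues", {
  asm <- generate_assembly(cluster_spec(
    anomalies = list(anomaly_truncate("elaB", 0.6)), seed = 8L))
  ref_n <- nchar(ela_reference()$proteins[["elaB"]])
  expect_identical(nchar(asm$proteins[["elaB"]]), as.integer(floor(0.6 * ref_n)))
  expect_identical(asm$truth$anomaly[asm$truth$gene == "elaB"], "truncated")
})

test_that("deleted genes are absent from the contig and flagged missing", {
  asm <- generate_assembly(cluster_spec(
    anomalies = list(anomaly_delete("elaT")), seed = 6L))
  row <- asm$truth[asm$truth$gene == "elaT", ]
  expect_false(row$present)
  expect_identical(row$anomaly, "missing")
  expect_false("elaT" %in% names(asm$proteins))
})

test_that("spec validation rejects inconsistent inputs", {
  expect_error(cluster_spec(genes = c("elaA", "elaA")), "unique")
  expect_error(cluster_spec(genes = "elaZ"), "unknown genes")
  expect_error(cluster_spec(divergence = 1.5), "divergence")
  expect_error(cluster_spec(anomalies = list(anomaly_reverse("elaQ"))),
               "absent gene")
  expect_error(cluster_spec(anomalies = list(anomaly_delete("elaB"),
                                             anomaly_truncate("elaB", 0.5))),
               "deleted gene")
  expect_error(cluster_spec(flank_length = -5), "flank_length")
})

test_that("mutate_protein substitutes exactly the rounded count of residues", {
  p <- random_protein(200, 11)
  for (d in c(0.05, 0.25, 0.5)) {
    m <- mutate_protein(p, d, seed = 21L)
    n_diff <- sum(strsplit(p, "")[[1]] != strsplit(m, "")[[1]])
    expect_identical(n_diff, as.integer(round(d * 200)))
  }
  expect_identical(mutate_protein(p, 0), p)
})
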