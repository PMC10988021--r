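test_that("a clean planted cluster is recovered gene-for-gene", {
  asm <- generate_assembly(cluster_spec(divergence = 0.1, seed = 101L))
  calls <- mine_assembly(asm$assembly)
  expect_length(calls, 1L)
  cl <- calls[[1]]
  expect_setequal(cl$genes$gene, ELA_GENES)
  expect_equal(cl$completeness, 1)
  expect_length(cl$anomalies, 0L)
  # mined coordinates equal the planted coordinates exactly
  tr <- asm$truth[match(cl$genes$gene, asm$truth$gene), ]
  expect_identical(cl$genes$start, tr$start)
  expect_identical(cl$genes$end, tr$end)
  expect_identical(cl$genes$strand, tr$strand)
})

test_that("assemblies lacking the precursor gene yield zero calls", {
  asm <- generate_assembly(cluster_spec(
    anomalies = list(anomaly_delete("elaA")), seed = 102L))
  expect_length(mine_assembly(asm$assembly), 0L)
})

test_that("clusters at or below half completeness yield zero calls", {
  # 4 genes present (< 5 required by the strict > 50% rule), elaA included
  asm <- generate_assembly(cluster_spec(
    genes = c("elaA", "elaP", "elaB", "elaC"), seed = 103L))
  expect_length(mine_assembly(asm$assembly), 0L)
  # 5 genes pass
  asm5 <- generate_assembly(cluster_spec(
    genes = c("elaA", "elaP", "elaB", "elaC", "elaT"), seed = 103L))
  calls <- mine_assembly(asm5$assembly)
  expect_length(calls, 1L)
  expect_equal(calls[[1]]$completeness, 5 / 9)
  expect_setequal(grep("^missing", calls[[1]]$anomalies, value = TRUE),
                  paste0("missing(", c("elaO", "elaI1", "elaI2", "elaI3"), ")"))
})

test_that("a frameshifted gene is called as a pseudogene", {
  # the retained 5' fragment must clear the 0.25-coverage rescue floor, so
  # the premature stop is planted past a third of the gene
  asm <- generate_assembly(cluster_spec(
    anomalies = list(anomaly_frameshift("elaC", 150L)), seed = 104L))
  calls <- mine_assembly(asm$assembly)
  expect_length(calls, 1L)
  expect_true("pseudogene(elaC)" %in% calls[[1]]$anomalies)
  expect_true("elaC" %in% calls[[1]]$genes$gene) # counts toward completeness
})

test_that("a truncated gene is flagged when coverage drops below 0.85", {
  asm <- generate_assembly(cluster_spec(
    anomalies = list(anomaly_truncate("elaB", 0.8)), seed = 105L))
  calls <- mine_assembly(asm$assembly)
  expect_length(calls, 1L)
  expect_true("truncated(elaB)" %in% calls[[1]]$anomalies)
})

test_that("reversed genes and reversed clusters are distinguished", {
  asm <- generate_assembly(cluster_spec(
    anomalies = list(anomaly_reverse("elaT")), seed = 106L))
  calls <- mine_assembly(asm$assembly)
  expect_true("reversed(elaT)" %in% calls[[1]]$anomalies)
  expect_false("reversed_cluster" %in% calls[[1]]$anomalies)

  asm2 <- generate_assembly(cluster_spec(
    anomalies = list(anomaly_reverse_cluster()), seed = 107L))
  calls2 <- mine_assembly(asm2$assembly)
  expect_length(calls2, 1L)
  expect_true("reversed_cluster" %in% calls2[[1]]$anomalies)
  expect_identical(calls2[[1]]$strand, "-")
  expect_false(any(grepl("^reversed\\(", calls2[[1]]$anomalies)))
})

test_that("similarity typing labels near-identical clusters and flags novel ones", {
  ref <- ela_reference()
  asm <- generate_assembly(cluster_spec(divergence = 0.02, seed = 108L))
  calls <- mine_assembly(asm$assembly)
  catalogue <- list(A37 = ref$proteins,
                    other = lapply(ref$proteins, mutate_protein,
                                   divergence = 0.4, seed = 999L))
  cls <- classify_cluster(calls[[1]], calls[[1]]$proteins, catalogue)
  expect_identical(cls$label, "A37")
  expect_gte(cls$mean_identity, 0.95)

  asm2 <- generate_assembly(cluster_spec(divergence = 0.25, seed = 109L))
  calls2 <- mine_assembly(asm2$assembly)
  cls2 <- classify_cluster(calls2[[1]], calls2[[1]]$proteins, catalogue)
  expect_identical(cls2$label, "novel")
  expect_identical(cls2$nearest, "A37")
})

test_that("classification errors when no gene can be scored", {
  asm <- generate_assembly(cluster_spec(seed = 110L))
  calls <- mine_assembly(asm$assembly)
  expect_error(
    classify_cluster(calls[[1]], calls[[1]]$proteins,
                     list(x = list(zzz = "MAAAA"))),
    "no scored gene")
})

test_that("cluster call tables flatten calls with 1-based coordinates", {
  asm <- generate_assembly(cluster_spec(seed = 111L))
  calls <- mine_assembly(asm$assembly)
  tab <- cluster_call_table(calls)
  expect_identical(nrow(tab), 9L)
  expect_identical(tab$start, calls[[1]]$genes$start + 1L)
  expect_true(all(tab$completeness == 1))
  expect_identical(nrow(cluster_call_table(list())), 0L)
})
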