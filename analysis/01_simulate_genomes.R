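#!/usr/bin/env Rscript

# Simulate a panel of synthetic assemblies carrying epilancin-like clusters
# at a range of divergences, with and without structural anomalies, and
# record the planted truth for downstream mining (02_mine_clusters.R).

suppressPackageStartupMessages(library(epilancr))

dir.create("results", showWarnings = FALSE)

panel <- list(
  list(name = "identical",       divergence = 0.00, anomalies = list()),
  list(name = "low_divergence",  divergence = 0.05, anomalies = list()),
  list(name = "mid_divergence",  divergence = 0.15, anomalies = list()),
  list(name = "high_divergence", divergence = 0.30, anomalies = list()),
  list(name = "frameshift_elaC", divergence = 0.10,
       anomalies = list(anomaly_frameshift("elaC", 150L))),
  list(name = "truncated_elaB",  divergence = 0.10,
       anomalies = list(anomaly_truncate("elaB", 0.8))),
  list(name = "reversed_elaT",   divergence = 0.10,
       anomalies = list(anomaly_reverse("elaT"))),
  list(name = "reversed_cluster", divergence = 0.10,
       anomalies = list(anomaly_reverse_cluster())),
  list(name = "missing_elaO_I2", divergence = 0.10,
       anomalies = list(anomaly_delete("elaO"), anomaly_delete("elaI2"))),
  list(name = "minimal_five_genes", divergence = 0.10, anomalies = list(),
       genes = c("elaA", "elaP", "elaB", "elaC", "elaT")))

truth_rows <- list()
for (i in seq_along(panel)) {
  p <- panel[[i]]
  spec <- cluster_spec(genes = if (is.null(p$genes)) ELA_GENES else p$genes,
                       divergence = p$divergence, anomalies = p$anomalies,
                       seed = 3200L + i)
  asm <- generate_assembly(spec)
  out_dir <- file.path("results", "assemblies")
  write_assembly(asm, out_dir, prefix = p$name)
  tr <- asm$truth
  tr$assembly <- p$name
  tr$divergence_planted <- p$divergence
  truth_rows[[i]] <- tr
}

truth <- do.call(rbind, truth_rows)
write.csv(truth, file.path("results", "01_planted_truth.csv"), row.names = FALSE)
cat("wrote", nrow(truth), "planted gene records for", length(panel),
    "assemblies\n")
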