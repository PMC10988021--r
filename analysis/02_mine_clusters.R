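#!/usr/bin/env Rscript

# Mine the simulated assemblies (01_simulate_genomes.R) for epilancin-like
# clusters, type each call against the bundled reference, and score gene
# presence against the planted truth.

suppressPackageStartupMessages(library(epilancr))

dir.create("results", showWarnings = FALSE)
truth <- read.csv(file.path("results", "01_planted_truth.csv"))
fastas <- list.files(file.path("results", "assemblies"), pattern = "\\.fna$",
                     full.names = TRUE)
if (!length(fastas)) stop("run analysis/01_simulate_genomes.R first")

catalogue <- list(A37 = ela_reference()$proteins)

call_rows <- list()
score_rows <- list()
for (fa in fastas) {
  name <- sub("\\.fna$", "", basename(fa))
  calls <- mine_assembly(read_fasta(fa))
  tab <- cluster_call_table(calls)
  if (nrow(tab)) {
    tab$assembly <- name
    tab$type <- vapply(seq_along(calls), function(i)
      classify_cluster(calls[[i]], calls[[i]]$proteins, catalogue)$label,
      character(1))[tab$cluster]
    call_rows[[name]] <- tab
  }
  found <- if (length(calls)) calls[[1]]$genes$gene else character(0)
  planted <- truth$gene[truth$assembly == name & truth$present]
  score_rows[[name]] <- data.frame(
    assembly = name, n_calls = length(calls),
    true_positive = length(intersect(found, planted)),
    false_positive = length(setdiff(found, planted)),
    false_negative = length(setdiff(planted, found)))
}

calls_tab <- do.call(rbind, call_rows)
scores <- do.call(rbind, score_rows)
scores$precision <- with(scores, ifelse(true_positive + false_positive > 0,
                                        true_positive / (true_positive + false_positive), NA))
scores$recall <- with(scores, ifelse(true_positive + false_negative > 0,
                                     true_positive / (true_positive + false_negative), NA))

write.csv(calls_tab, file.path("results", "02_cluster_calls.csv"), row.names = FALSE)
write.csv(scores, file.path("results", "02_mining_scores.csv"), row.names = FALSE)
cat(sprintf("overall precision %.3f, recall %.3f over %d assemblies\n",
            sum(scores$true_positive) / sum(scores$true_positive + scores$false_positive),
            sum(scores$true_positive) / sum(scores$true_positive + scores$false_negative),
            nrow(scores)))
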