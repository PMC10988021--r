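#!/usr/bin/env Rscript

# Maturation bookkeeping for the synthetic epilancin core: leader cleavage,
# the full canonical modification set, and the mass deltas of the individual
# modification steps.

suppressPackageStartupMessages(library(epilancr))

dir.create("results", showWarnings = FALSE)
ref <- ela_reference()

core <- cleave_leader(paste0(ref$leader, ref$core), cleavage = "AASSPQ")$core
stopifnot(core == ref$core)

unmod <- apply_maturation(core)
mature <- apply_maturation(core, ela_modifications())

# step-wise variants for the reported deltas
m <- ela_modifications()
dehydr_only <- apply_maturation(core, modification_set(dehydrated = m$dehydrated))
no_lac <- apply_maturation(core, modification_set(
  dehydrated = m$dehydrated, rings = m$rings, abu = m$abu))
plus_ch2 <- apply_maturation(core, modification_set(
  dehydrated = m$dehydrated, rings = m$rings, lactate = TRUE, abu = m$abu,
  methylations = 1L))

species <- list(
  unmodified_core = unmod,
  dehydrated_only = dehydr_only,
  mature_no_lactate = no_lac,
  mature = mature,
  mature_plus_ch2 = plus_ch2)

masses <- data.frame(
  species = names(species),
  average_da = vapply(species, `[[`, numeric(1), "average"),
  monoisotopic_da = vapply(species, `[[`, numeric(1), "monoisotopic"),
  row.names = NULL)

deltas <- data.frame(
  step = c("per_dehydration", "lactate_cap", "one_methylation",
           "total_maturation"),
  delta_average_da = c(
    (dehydr_only$average - unmod$average) / length(m$dehydrated),
    mature$average - no_lac$average,
    plus_ch2$average - mature$average,
    mature$average - unmod$average))

segments <- data.frame(segment = names(mature$segments),
                       length = unname(mature$segments))
residues <- data.frame(position = seq_len(nchar(core)),
                       residue = strsplit(core, "")[[1]],
                       state = mature$residues)

write.csv(masses, file.path("results", "03_species_masses.csv"), row.names = FALSE)
write.csv(deltas, file.path("results", "03_mass_deltas.csv"), row.names = FALSE)
write.csv(segments, file.path("results", "03_ring_segments.csv"), row.names = FALSE)
write.csv(residues, file.path("results", "03_residue_states.csv"), row.names = FALSE)
cat(sprintf("mature core: average %.3f Da, monoisotopic %.3f Da\n",
            mature$average, mature$monoisotopic))
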