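---
title: "Methods: models, conventions and numerical choices in epilancr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and numerical choices in epilancr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epilancr)
```

epilancr is an analysis workbench for staphylococcal epilancin lantibiotics.
Every pipeline stage is paired with a synthetic-data generator that records
the full planted ground truth, so each method can be validated as a closure:
simulate with known parameters, analyse, and compare the recovered quantities
to the planted ones. This vignette documents the models, conventions and
numerical choices behind each module, and the limits of the synthetic data.

## The bundled synthetic reference cluster

The nine-gene epilancin cluster (`ELA_GENES`) comprises the precursor
`elaA`, protease `elaP`, dehydratase `elaB`, cyclase `elaC`, transporter
`elaT`, the leader-peptidase/dehydrogenase `elaO`, and immunity genes
`elaI1`–`elaI3`. Because no producer genome is bundled, the reference
proteins are synthetic: `elaA` is hand-designed with an epilancin-like
30-residue core and the canonical ring topology, and the remaining proteins
are fixed pseudo-random sequences of plausible lengths drawn once under a
frozen internal seed. Coding sequences are back-translated with a fixed
AT-rich codon table; mining operates at the protein level, so the choice of
table is immaterial. Consequences: absolute sequence content is not
biological, but lengths, gene order and the precursor architecture are
realistic, which is what the mining and phylogeny methods actually consume.

## Synthetic genomes

`cluster_spec()`/`generate_assembly()` plant a cluster in a random
background contig. Divergence `d` substitutes exactly `round(d * n)`
residues per protein (initiator Met pinned), so planted identity is known to
within one residue. Anomalies are explicit operators: frameshift (single
base insertion creating a premature stop), truncation, per-gene reversal,
whole-cluster reversal, and deletion. Truth tables use 0-based half-open
coordinates internally; the reporting table (`cluster_call_table()`) is
1-based inclusive.

## Cluster mining

Six-frame ORF calling accepts ATG/GTG/TTG starts and reports 0-based
half-open genomic coordinates on both strands. Translated ORFs are screened
against the reference proteins by Smith–Waterman with BLOSUM62 and affine
gaps (open 11, extend 1; a gap of length L costs `open + (L-1)*ext`,
matching blastp's convention). Hits pass at reference coverage > 0.70; hits
with coverage in (0.25, 0.70] and identity ≥ 0.45 form a partial tier from
which pseudogenes are rescued when the ORF stops well before the reference
end (< 0.9 of reference length). Genes hit by several ORF fragments are
in-frame broken genes and are likewise annotated as pseudogenes. Calls
require strictly more than half of the reference genes present *and* the
precursor `elaA`; coverage in (0.70, 0.85] is annotated `truncated`,
minority-strand members `reversed`, and a majority-minus cluster
`reversed_cluster`. Typing against a catalogue uses mean per-gene identity
with a 0.95 threshold for a known label, else `"novel"`.

A known limit: a frameshift very early in a gene can leave a 5' fragment
below the 0.25-coverage rescue floor, in which case the pseudogene is
reported as missing. The synthetic panels therefore place frameshifts where
a diagnosable fragment remains.

## Maturation and mass bookkeeping

Masses are computed from per-residue atomic compositions (C, H, N, O, S)
with IUPAC average and monoisotopic atomic weights; a peptide of n residues
loses n−1 waters. Modifications are composition deltas: dehydration −H₂O
(Ser→Dha, Thr→Dhb), thioether ring formation mass-neutral (the dehydration
already happened), the N-terminal lactyl cap net −N+H+O relative to Dha,
Thr→Abu net −O, and each C-methylation +CH₂. `validate_mods()` enforces the
chemistry: ring donors must be dehydrated Ser/Thr preceding their Cys
acceptor, no Cys in two rings, lactate only on a dehydrated N-terminal Ser.
Ring topology is summarised as alternating linear/ring-system segments;
overlapping rings merge into one intertwined system (the synthetic core
yields segments 11/5/3/5/6).

## Phylogeny

Cluster phylogenies concatenate per-gene CDS in reference order, padding
absent genes with all-gap slots of the reference length; `elaO` is omitted
by default (its dual role makes it a poor phylogenetic marker, and omission
keeps concatenations shorter). Progressive alignment uses a 6-mer distance
UPGMA guide tree and profile–profile Needleman–Wunsch (match 1, mismatch −1,
gap −2) with expected-score column scoring, implemented in C++ with a
rolling-row DP so memory stays linear in sequence length. Distances are
p-distances over mutually ungapped sites. Neighbor joining is implemented
directly (Q-criterion, lowest-index tie-break, negative branch estimates
clamped to zero and counted); `ape` is used only to parse the Newick string
and for tree utilities.

Horizontal-transfer simulations (`transfer_scenario()`) grow two cluster
lineages from a common ancestor (default divergence 0.2) and sample members
(within-lineage divergence 0.02) interleaved across host labels, so grouping
by host order is guaranteed wrong. The default problem size — three short
genes, six taxa — keeps one replicate under a second, so recovery fractions
can be estimated over 100 seeds in seconds; recovery is lineage monophyly in
the unrooted tree.

## Synthetic microscopy and single-cell quantification

Cells are spherocylinders in micrometre coordinates (default 0.05 µm/px,
256×256): a pixel belongs to a cell when the distance from its centre
(pixel i centred at (i−0.5)·px) to the cell's axis segment is below half the
width. Scenes add uniform cytoplasmic intensity, optional membrane bands and
Gaussian spots, a Gaussian PSF blur, and optional Poisson/Gaussian noise;
the truth records the unblurred mask, per-cell parameters and spot
positions. Scenes refuse overlapping cells, so closure metrics are
well-defined.

Segmentation smooths (σ = 1 px), Otsu-thresholds, fills holes, and splits
touching cells by distance-map watershed (tolerance 2). Because a single
global threshold erodes dim cells when brightnesses vary, each watershed
region is then refined to its own half-maximum threshold
(background + 0.5·(cell median − background)), with contested pixels
assigned by propagation. Geometry (centroid, principal-axis angle, length,
width) comes from mask second moments. Spot detection finds strict local
maxima of the σ = 1 px smoothed image, keeps those whose prominence over the
owning cell's median exceeds `min_prominence` times that median, and merges
maxima closer than the PSF. Spot positions are reported in normalized cell
coordinates (signed long/transverse offsets and pole-normalized folds).

Per-cell intensity is the background-subtracted mask mean. This closes
exactly on unblurred scenes; under PSF blur, edge pixels mix cell and
background and the closure degrades to ~1–2%, so quantitative intensity
validation uses unblurred scenes by design.

## Colocalization and GUVs

Two-channel scenes share the cell structure and add standardized smooth
random fields mixed with weight `coloc` (channel B gets
`coloc·F1 + sqrt(1−coloc²)·F2`), and the truth records the exact Pearson
correlation of the clean channels, both in-mask and per cell — the per-cell
values are the correct closure targets because the shared cell structure
inflates the pooled correlation. `pcc_per_cell()` excludes zero-variance
cells explicitly.

GUV images are membrane annuli over interior/exterior plateaus. Ring
fitting seeds a Kasa algebraic circle fit with Otsu-thresholded gradient
pixels and refines centre and radius by maximizing mean interpolated
on-circle intensity (Nelder–Mead, deterministic start); under σ = 2 px blur
the fitted radius is within a fraction of a pixel. Radial profiles average
bilinear samples over 720 rays at offsets −50..+50 px from the membrane,
normalized to their own maximum, with centre-clipped offsets counted.

## Assay statistics

MIC calls on 2-fold series return the lowest no-growth concentration,
`">max"` when growth persists to the top, a range string (e.g. `"16–32"`)
when replicates disagree, and place non-monotone patterns just above the
highest growth well with a flag. Dye-release traces take the baseline as the
mean of the last 5 min before addition and the plateau as the first
post-addition time whose forward 2-min window (which must fit inside the
trace) varies less than a tolerance defaulting to 2% of the dynamic range.
Group comparisons are unpaired two-tailed Student's t-tests
(pooled variance; Welch behind a flag) via `stats::t.test`, with star bins
ns/\*/\*\*/\*\*\*/\*\*\*\* at 0.05/0.01/0.001/0.0001; the 0.01, 0.001 and
0.0001 boundaries belong to the more significant bin and p = 0.05 exactly is
"ns".

## Reproducibility

All generators are deterministic functions of an integer seed (< 2³¹), and
seeded code restores the caller's RNG state. The numbered scripts under
`analysis/` regenerate the result tables in `results/`, and
`scripts/acceptance.R --seed <int> --out <path>` runs every stage against
its planted truth and writes the headline quantities as JSON.
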