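# epilancr

Epilancin gene-cluster mining, lanthipeptide maturation modelling and
single-cell fluorescence quantification.

Epilancins are staphylococcal lantibiotics: ribosomally synthesized peptides
whose precursor (the product of `elaA`) is matured by dehydration of Ser/Thr
residues, lanthionine ring formation onto Cys acceptors, and an unusual
N-terminal lactyl cap, then exported and cleaved from its leader. Producers
carry a compact biosynthetic gene cluster — precursor, protease,
dehydratase, cyclase, transporter, leader-peptidase/dehydrogenase and
immunity genes — that can be recognised in genome assemblies by homology.
Downstream of genomics, the compound's mode of action is studied by
fluorescence microscopy (membrane accumulation spots in single cells,
colocalization between channels, giant unilamellar vesicle binding) and by
plate assays (MIC series, voltage-dye release, competition).

epilancr implements that entire workflow on a synthetic, fully
ground-truthed basis:

- **Synthetic genomes** — plant an epilancin-like cluster at a chosen
  divergence, with frameshifts, truncations, reversals or deletions, and
  record exact coordinates and identities (`cluster_spec()`,
  `generate_assembly()`).
- **Cluster mining** — six-frame ORF calling, Smith–Waterman/BLOSUM62
  homology screening, coverage/completeness filters, pseudogene rescue,
  anomaly annotation and similarity-based typing (`mine_assembly()`,
  `cluster_call_table()`, `classify_cluster()`).
- **Maturation** — composition-level bookkeeping of dehydrations, rings,
  lactate, Abu and methylations, with average and monoisotopic masses
  (`apply_maturation()`, `ela_modifications()`, `cleave_leader()`).
- **Phylogeny** — concatenated-gene progressive alignment (C++ profile DP),
  p-distances and an in-package neighbor-joining implementation, plus
  horizontal-transfer recovery simulations (`cluster_phylogeny()`,
  `transfer_scenario()`).
- **Synthetic microscopy** — spherocylinder cell scenes, two-channel fields
  with a planted Pearson correlation, and GUV ring images, each with full
  truth (`cell_scene()`, `render_two_channel()`, `render_guv()`).
- **Single-cell quantification** — segmentation with per-cell half-maximum
  refinement, per-cell intensity, spot detection in normalized cell
  coordinates (`segment_cells()`, `detect_maxima()`, `map_to_cell_frame()`).
- **Colocalization & GUVs** — per-cell Pearson coefficients, ring fitting,
  membrane-centred radial profiles (`pcc_per_cell()`, `fit_guv()`,
  `radial_profile()`).
- **Assay statistics** — MIC calling with above-range and replicate-range
  semantics, dye-release plateau summaries, Student's t-tests with
  significance-star binning (`mic_call()`, `disc_summary()`,
  `ttest_groups()`).

See `vignettes/epilancr-methods.Rmd` for the models, conventions and
numerical choices behind each module.

## Worked example

Plant a cluster at 15% divergence with a truncated dehydratase, mine it
back, and type the call:

```r
library(epilancr)

spec <- cluster_spec(divergence = 0.15,
                     anomalies = list(anomaly_truncate("elaB", 0.8)),
                     seed = 42L)
asm <- generate_assembly(spec)
calls <- mine_assembly(asm$assembly)
cluster_call_table(calls)
#>   cluster   contig  gene start  end strand  identity  coverage completeness
#> 1       1 contig_1  elaA  1001 1168      + 0.8545455 1.0000000            1
#> 2       1 contig_1  elaP  1219 2091      + 0.8517241 1.0000000            1
#> 3       1 contig_1  elaB  2142 3584      + 0.8625000 0.8000000            1
#> 4       1 contig_1  elaC  3635 4957      + 0.8500000 1.0000000            1
#> 5       1 contig_1  elaT  5008 6570      + 0.8535645 0.9980769            1
#> 6       1 contig_1  elaO  6621 7553      + 0.8516129 1.0000000            1
#> 7       1 contig_1 elaI1  7604 7966      + 0.8500000 1.0000000            1
#> 8       1 contig_1 elaI2  8017 8439      + 0.8500000 1.0000000            1
#> 9       1 contig_1 elaI3  8490 8747      + 0.8588235 1.0000000            1
#>         anomalies
#> 1 truncated(elaB)
#> ...
```

All nine genes are recovered at their planted coordinates; the 80%
truncation of `elaB` surfaces as coverage 0.80 and a `truncated(elaB)`
annotation. At ~15% divergence the call types as novel relative to the
bundled reference:

```r
classify_cluster(calls[[1]], calls[[1]]$proteins,
                 list(A37 = ela_reference()$proteins))
#> $label
#> [1] "novel"
#> $nearest
#> [1] "A37"
#> $mean_identity
#> [1] 0.8539757
```

Mature the synthetic core with the canonical modification set (6
dehydrations, 3 rings, N-terminal lactate, one Abu):

```r
mat <- apply_maturation(ELA_CORE, ela_modifications())
sprintf("%.3f Da average, %.3f Da monoisotopic", mat$average, mat$monoisotopic)
#> [1] "3067.737 Da average, 3065.624 Da monoisotopic"
mat$segments
#>    n_terminal ring_system_1       hinge_1 ring_system_2    c_terminal
#>            11             5             3             5             6
```

## Analysis workflow

The numbered scripts under `analysis/` regenerate all result tables in
`results/` from the package root:

```sh
Rscript analysis/01_simulate_genomes.R   # assemblies + planted truth
Rscript analysis/02_mine_clusters.R      # calls, typing, precision/recall
Rscript analysis/03_maturation.R         # species masses and step deltas
Rscript analysis/04_phylogeny.R          # panel tree, transfer recovery
Rscript analysis/05_cell_imaging.R       # segmentation/spot closure
Rscript analysis/06_coloc_guv.R          # colocalization + GUV fits
Rscript analysis/07_assays_stats.R       # MIC, DiSC, group tests
```

## License

MIT (see `LICENSE`).
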