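Package: epilancr
Title: Epilancin Gene-Cluster Mining, Maturation Modelling and Single-Cell
    Fluorescence Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis workbench for staphylococcal epilancin lantibiotics.
    Mines genome assemblies for epilancin-like biosynthetic gene clusters
    (six-frame ORF calling, Smith-Waterman homology screening, coverage and
    completeness filters, anomaly annotation, similarity-based typing), models
    lanthipeptide maturation (leader cleavage, Ser/Thr dehydration, lanthionine
    ring formation, N-terminal lactate) with average and monoisotopic mass
    prediction, builds concatenated-gene neighbor-joining cluster phylogenies,
    and quantifies single-cell fluorescence microscopy: cell segmentation,
    per-cell intensity, accumulation-spot detection in normalized cell
    coordinates, Pearson colocalization, and giant unilamellar vesicle ring
    fitting with membrane-centered radial profiles. Ships synthetic genome and
    synthetic microscopy-scene generators with full planted ground truth, so
    every stage is testable end to end, plus the plate-assay statistics used
    alongside (MIC calling, dye-release summaries, unpaired t-tests with
    significance-star binning).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    Rcpp,
    ape,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
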