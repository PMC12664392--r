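Package: epiScan
Title: Specificity Profiling and Cross-Reactivity Screening for Peptide-Centric T Cell Engagers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the target specificity of binders that
    recognise HLA class I / peptide complexes, such as DARPin-based T cell
    engagers. Positional-scanning (X-scan and alanine-scan) T cell activation
    matrices are averaged across replicates, normalized to the wild-type
    residue at each position, and thresholded into per-position tolerance
    profiles that serialize to PROSITE-style peptide motifs. Motifs are
    scanned against proteome FASTA files to enumerate candidate
    cross-reactive epitopes. Companion assay arithmetic implements HTRF
    specificity-ratio hit calling, three-parameter log(agonist)
    dose-response fitting with EC90 derivation, and chromium-release percent
    specific lysis. A structural module computes Shrake-Rupley solvent
    accessible surface areas, buried interface areas between two chain
    groups, per-residue footprints, typed atomic contacts, backbone
    contributions, and Kabsch superposition RMSD on PDB/mmCIF models.
    Simulators generate every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    jsonlite,
    minpack.lm,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'assay.R'
    'epiScan-package.R'
    'structure.R'
    'sasa.R'
    'interface.R'
    'motif.R'
    'simulate.R'
    'superpose.R'
    'xscan.R'
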