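Package: hicCurator
Title: Automated Curation of Hi-C Scaffolded Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and correcting structural misassemblies
    (translocations, inversions, debris) in Hi-C scaffolded genomes.
    Provides a multi-resolution contact-matrix store with sliding-window
    heatmap tiling, pixel-to-genome coordinate mapping for bounding-box
    detectors, a peak-voting algorithm that locates translocation
    insertion sites from contact profiles, an editor for 3D-DNA style
    '.assembly' documents (cut, move, invert, relegate, FASTA export),
    chromosome-territory assignment from global contact maps, assembly
    QC report statistics (Nx/Lx, CC ratio, structural error rates,
    anchor rate), detector evaluation metrics (IOU, confusion matrix,
    AUPRC), and a synthetic misassembly plus distance-decay contact-map
    simulator with a ground-truth oracle detector that makes the full
    iterative detect-correct-assign loop testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    pracma,
    png,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
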