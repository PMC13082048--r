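Package: rnapcollide
Title: Structural and Biochemical Analysis of Transcriptional Collisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of RNA polymerase collision structures and the
    biochemistry around them. Measures the swivel-module rotation angle of an RNA
    polymerase elongation complex relative to a reference by rigid-body (Kabsch)
    superposition and axis-angle extraction; builds a principal-component reference
    frame over downstream-DNA nucleotide centers of mass and projects DNA
    displacement onto it; walks a structure stepwise along the B-DNA helical axis
    and scores steric conflict with a fixed roadblock via solvent-excluded-surface
    overlap volumes on voxel grids; quantifies roadblocking efficiency from gel lane
    intensities and complex stability from bi-exponential decay fits with bootstrap
    confidence intervals; classifies paired 5'/3' RNA reads by summed local
    alignment scores with distance and start-site filters; and generates synthetic
    structures, helices, reads and assay tables with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
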