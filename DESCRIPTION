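Package: edgesense
Title: Quantification of Cell-Edge Polarity, Interactome Ranking and Root
    Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying edge-polarized membrane proteins
    in plant roots. Ranks candidate interactors from comparative
    co-immunoprecipitation label-free proteomics (bait-completeness
    filtering, half-minimum imputation, SAM-style S0 volcano enrichment with
    permutation false-discovery control, and multi-criterion super-ranking);
    quantifies confocal fluorescence images (hysteresis background removal,
    Manders colocalization per 25 um region, distance-from-edge intensity
    profiles with a Tukey-based significance distance, and post/pre ablation
    intensity ratios); and measures lateral-root maximum diameter from
    two-sided outline traces by nearest-neighbour distances. Includes
    seeded synthetic-data generators (LFQ matrices with planted interactors,
    polyhedral-cell confocal phantoms, ablation pairs, root outlines) so
    every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
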