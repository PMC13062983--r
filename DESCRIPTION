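Package: embryoTrace
Title: Visualization and Batch Processing of C. elegans Embryo Cell-Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with Caenorhabditis elegans embryo cell-tracking
    tables as produced by the StarryNite/AceTree pipeline. Reads and writes the
    tabular "CD" dialect, raw StarryNite zip archives and TIME stamp files;
    converts pixel/plane coordinates to microns; searches cells by Sulston
    lineage nomenclature including single-letter wildcards; fits and applies a
    rigid-body rotation to a canonical anatomical orientation using PCA plus
    landmark cell groups; learns and applies an exponential depth-attenuation
    correction for reporter expression across replicate embryos; aligns
    developmental time across embryos by lineage events; extracts per-lineage
    expression trajectories; and renders 3D nuclear-position plots, lineage
    trees colored by expression (SVG) and trajectory figures, with a batch
    command-line front end. A synthetic-embryo simulator with known ground
    truth supports testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
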