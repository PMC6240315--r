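Package: nmlineage
Title: Clonal and Single-Cell Lineage Analysis of Zebrafish Neuromesodermal Progenitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements, as tested and reusable components, the three
    computational procedures behind a zebrafish neuromesodermal-progenitor
    lineage study: CRISPR scar (ScarTrace) clonal analysis with staged scar
    filtering, binarization, an information-weighted sparse-sample distance,
    clustered log-distance heatmaps and bootstrapped neighbor-joining trees;
    in-silico photolabelling and reporter-based fate classification on
    cell-tracking lineage forests with terminal-division scoring; and the 3D
    phase-correlation registration loop used for online light-sheet stage
    tracking of the elongating tailbud. Each procedure is paired with a
    synthetic-data generator (scarred embryo division trees, fate-committing
    lineage forests, drifting image volumes) so the full pipeline runs and is
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    igraph,
    phangorn,
    pheatmap,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
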