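Package: ConnectomeView
Title: Visualization and Graph Analysis of Human Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Loads human brain connectivity networks (adjacency matrix plus
    parcellation plus ROI ordering file), computes nodal and global
    graph-theoretic statistics including a spectral modular decomposition
    with fine-tuning, and renders three linked visualization styles (3D
    node-link brain, connectivity matrix heatmap, circular connectogram) to
    deterministic static images. Parcellations may be given as surface
    parcels (FreeSurfer or GIFTI), labeled segmentation volumes (NIFTI or
    MGZ) with a structure lookup, or plain coordinate tables. Includes a
    synthetic fixture generator producing complete toy datasets so the
    whole pipeline is testable without any neuroimaging downloads, and a
    command-line front end for scripted use.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    png,
    xml2,
    RNifti,
    optparse
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
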