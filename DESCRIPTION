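Package: wingpol
Title: Planar Cell Polarity Modeling and Microtubule Image Quantification
    for the Insect Wing Epithelium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the coupling between the Fat/Dachsous/Four-jointed
    global module and the core planar cell polarity (PCP) feedback loop on a
    hexagonal cell lattice: tissue-level Dachsous and Four-jointed gradients
    set junctional Fat-Dachsous heterodimer asymmetry, which biases an apical
    microtubule network that directs Dishevelled transport, polarizing the
    core loop. Includes the companion quantification toolkit for such
    experiments: structure-tensor orientation fields and axial rose-plot
    histograms for tubulin-like fiber images, cross-correlation shift
    colocalization with proximal/distal peak asymmetry, circular statistics
    for microtubule anchoring sites, and net-direction/motion-mode
    classification of vesicle tracks with exact binomial direction tests.
    Ships synthetic-data generators with machine-readable ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
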