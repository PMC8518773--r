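Package: biocrustmap
Title: Terrain, Thermal Inertia and Spectral Mapping of Dryland Biocrust Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying how terrain attributes and soil
    moisture control the distribution of biological soil crusts (biocrusts) in
    drylands from fine-resolution UAV-style rasters. Derives terrain attributes
    from a digital terrain model (Zevenbergen-Thorne slope and aspect,
    northernness, priority-flood pit removal, D-infinity flow accumulation,
    topographic wetness index, length-slope factor, annual clear-sky potential
    solar radiation); calibrates raw multispectral digital numbers to
    reflectance with an empirical-line correction; classifies green/red/
    red-edge/NIR imagery into seven surface covers with a continuum-removal
    refinement of the chlorophyll absorption at 660 nm; computes apparent
    thermal inertia from pre-dawn/noon thermal pairs as a soil-moisture proxy;
    and runs plot- and landscape-level statistics (correlation ratio with
    tercile binning, Kruskal-Wallis with Dunn's post hoc, redundancy analysis
    with marginal permutation tests and VIF screening). A synthetic scene
    generator with known ground truth makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    sandwich,
    jsonlite
Config/testthat/edition: 3
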