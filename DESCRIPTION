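Package: chemotaxr
Title: Micropipette Chemotaxis and Calcium Imaging Analysis for iPSC-Derived Microglia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies directed migration of human iPSC-derived microglia (iMG)
    toward a pulsed micropipette point source of ADP, together with the
    ratiometric calcium responses that accompany it. Provides a closed-form
    pulsed point-source diffusion model of the chemoattractant gradient, a
    biased persistent random-walk generator with treatment presets that emulate
    the assay's pharmacological and genetic perturbations, synthetic time-lapse
    rendering with ground truth, a segmentation/linking/curation tracking chain,
    radially binned migration statistics (directed-migration efficiency, speed,
    line speed to the tip, straightness, mean squared displacement), and
    ratiometric Ca2+ metrics (delta-R/R0, amplitude, integral, rise time,
    store-operated Ca2+ entry rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
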