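Package: synaptoscreen
Title: High-Content Live-Neuron Synapse Screening by Puncta Detection and
    Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies bipartite synapses in two-channel fluorescence
    microscopy of live neuronal cultures expressing presynaptic
    (VAMP2-mRFP-like) and postsynaptic (PSD95-mVenus-like) markers.
    Implements the four-stage detection chain used in high-content
    screening of synaptotoxicity: template-matching alignment of serial
    acquisitions of the same imaging site, background flattening,
    no-neighbors deconvolution, top-hat filtering, maximum-entropy or Otsu
    thresholding, size-filtered particle counting, and pre/post punctum
    colocalization. Aggregates site counts to wells and plates, computes
    baseline-normalized synapse loss, and tests treated wells against
    no-treatment controls with Dunnett and Tukey multiplicity-adjusted
    comparisons. Ships a synthetic two-channel field and plate generator
    with full ground truth (punctum positions, colocalization pairs,
    stage shifts, treatment effect sizes) for validation and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    multcomp,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
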