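Package: kelpCSP
Title: Carbon Export, Decomposition and Sequestration Potential of Kelp Forests
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the particulate carbon flux of Laminaria
    kelp forests from field-style measurements: hole-punch lamina erosion to
    per-plant and areal carbon export, litterbag decomposition rates,
    closed-bottle respirometry (NPP, R, GPP and carbon assimilation with blank
    correction and photoinhibition screening), phenolic quantification from a
    phloroglucinol standard curve, and detrital-age biochemistry trends. A
    linear carbon-sequestration-potential (CSP) decay model with
    product-of-means confidence intervals ties the budget together, and is
    projected through time from sea-surface-temperature trajectories and
    species thermal thresholds. Cumulative detrital carbon assimilation along
    a sinking trajectory is estimated from a tanh photosynthesis-irradiance
    curve and exponential light attenuation. A synthetic-data generator
    emulates the full field design so the pipeline runs end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
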