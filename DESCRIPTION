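Package: plasmidkin
Title: Kinetics of Radiation-Induced Plasmid DNA Damage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the cell-free plasmid DNA damage assay: closed-form
    Bateman-type kinetics of the supercoiled -> relaxed -> linear topology
    conversion under irradiation, global weighted nonlinear least-squares
    estimation of the conversion rates from agarose-gel band percentages,
    and a calculator relating external-beam dose to radionuclide incubation
    time producing equal modelled DNA damage, with delta-method uncertainty
    propagation. Includes gel-lane densitometry (profile extraction,
    baseline subtraction, band quantification) and generators of synthetic
    band-percentage tables and gel images for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    pracma,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
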