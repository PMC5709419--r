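Package: metalsens
Title: Thermodynamic Modelling of Bacterial Metal-Sensor Specificity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to analyse how bacterial metalloregulatory transcription
    factors (Zur, ZntR, RcnR, FrmR) discriminate between zinc and cobalt.
    Solves coupled sensor/metal/DNA/buffer binding equilibria under total
    concentration mass balances, computes allosteric coupling free energies
    from apo- and holo-sensor DNA affinities, predicts fractional
    operator-promoter occupancy as a function of the buffered intracellular
    metal concentration, and extracts sensor set points and response orders.
    Also simulates and fits the underlying in vitro experiments: chelator
    competition titrations for metal affinities and fluorescence anisotropy
    titrations for DNA affinities, with seeded synthetic data generators for
    every experimental design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
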