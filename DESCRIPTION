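Package: quenchcal
Title: Calibration of Rhodamine Self-Quenching as a Short-Range Distance Probe
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating tetramethylrhodamine (TMR) self-quenching
    as a 15-25 Angstrom proximity probe on polyproline-II molecular rulers.
    Builds idealised Cys-(Pro)n-Cys ruler structures, computes dye-accessible
    volumes and mean dye positions, decomposes absorption spectra into
    monomer and H-dimer components under the exciton framework, fits the
    fluorescence-versus-distance calibration with a Hill-form response,
    performs instrument-response reconvolution fitting of time-correlated
    single photon counting (TCSPC) decays with globally shared lifetimes,
    and fits fluorescence correlation spectroscopy (FCS) curves with a
    diffusion-plus-triplet model including timescale-bound inference for
    undetected relaxations. A synthetic-data module generates decays,
    correlation curves, spectra and calibration tables with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
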