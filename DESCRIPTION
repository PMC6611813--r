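Package: zulfspin
Title: Zero- to Ultralow-Field NMR J-Spectra of Chemically Exchanging Spin Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative simulation of nuclear magnetic resonance J-spectra
    of chemically exchanging spin-1/2 systems at zero-to-ultralow field and
    at high field. Couples two-species chemical kinetics to Liouville-space
    spin dynamics in a combined Bloch-McConnell-type generator with
    dissociation (partial-trace) and association (bath-attachment)
    superoperators, fluctuating-field relaxation calibrated to high-field T1,
    and propagation by matrix exponentiation. Includes measurement-protocol
    simulators (prepolarize-shuttle-detect and high-field pulse-acquire),
    spectral analysis, a Markov-chain model of nuclear-spin memory loss under
    proton exchange, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
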