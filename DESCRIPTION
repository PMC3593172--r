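Package: perfusiontwin
Title: Digital Twin of a Hardware Myocardial First-Pass Perfusion Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulates first-pass myocardial perfusion measurements as
    performed on a physiologically sized hardware flow phantom: bolus
    dilution of a gadolinium contrast agent through a cascade of cardiac
    chambers and thoracic vessels, saturation-recovery gradient-echo
    signal generation with dose-dependent T1 saturation, and absolute
    perfusion quantification by dual-bolus Fermi-function constrained
    deconvolution. Includes the experiment protocols used to characterise
    such a phantom (contrast-dose series, perfusion-rate series,
    cardiac-output sensitivity, and reproducibility runs) together with
    their summary statistics, plus a synthetic dynamic image renderer
    with region-of-interest extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
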