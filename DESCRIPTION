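Package: saiopt
Title: Components-Knockout Proportion Optimization for Multicomponent Injections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for optimizing the component proportion of a
    multicomponent herbal injection (sodium aescinate injection) from HPLC
    fingerprint peak-area tables and bioassay readouts. Provides peak-table
    arithmetic (relative areas, per-component dosages, ten-point proportions),
    gray correlation analysis (Deng relational coefficients and grades) to rank
    component effectiveness and irritation, a four-layer backpropagation
    neural-network surrogate mapping component dosages to absorbance and ear
    swelling ratio, and an inverse Monte Carlo optimizer that screens candidate
    proportions against response criteria and forms a consensus proportion.
    Includes a synthetic dose-response data generator with known ground truth
    so every stage is testable without animal data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
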