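Package: hrmscreen
Title: Suspect and Target Screening of LC-HRMS Data for Antioxidant Beverages
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A dual suspect/target screening toolkit for centroided LC-HRMS
    runs of antioxidant-rich beverages. Implements molecular-formula and adduct
    m/z arithmetic, combinatorial enumeration of virtual metabolites
    (glycosylation and methylation products), suspect-list and MSP spectral
    database handling, MS1-driven targeted extracted-ion-chromatogram
    screening with procedure-blank filtering, DDA and DIA fragmentation
    matching by cosine similarity, Schymanski-style identification confidence
    levels (1, 2a, 2b, 3, 4, 5), and external-calibration quantification with
    limit-of-quantification flagging. Ships a seeded synthetic-run generator
    emulating pomegranate-based juice samples and a procedure blank for
    end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tools
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
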