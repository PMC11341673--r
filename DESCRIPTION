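Package: amphistomy
Title: Leaf Dorsiventral CO2 Gradients from Epicuticular Wax Carbon Isotopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the adaxial-abaxial CO2 concentration gradient of a leaf
    from the carbon-isotope polarity of its epicuticular wax, quantifies
    stomatal and wax patterning between leaf sides (amphistomy and amphiwaxy
    levels and their regression-derived asymptotes), and separates direct
    from light- or age-mediated associations between amphistomy and isotopic
    polarity using least squares with a cluster bootstrap. Includes a forward
    generator of study-shaped synthetic datasets with known ground truth so
    every pipeline stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
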