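Package: vinemites
Title: Management, Landscape and Food-Resource Drivers of Vineyard Mite Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how local vineyard management (pesticide
    toxicity load, inter-row cover-crop type) and surrounding landscape
    composition shape predatory mite, phytophagous mite and leaf-surface
    pollen densities. Implements the area-related acute pesticide contact
    toxicity loading (aAPTLc) index and a categorical toxicity rating for
    Typhlodromus pyri from spray records, density normalisation for
    leaf-wash mite counts and sticky-tape pollen counts, landscape
    composition percentages with Shannon landscape diversity, a
    small-sample AICc multi-model inference workflow over Gaussian GLMs
    with collinearity and VIF screening, Spearman correlation and NMDS
    ordination with environmental trait fitting, and a synthetic
    paired-vineyard study generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
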