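Package: encaland
Title: Ecosystem Natural Capital Accounting for Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Biophysical ecosystem accounting for a protected area or any
    bounded landscape: diachronic land-cover stock and flow accounts,
    socio-ecological landscape units (SELUs) built from sub-watersheds and
    dominant land cover, ecosystem water, carbon and infrastructure
    functional-service accounts with their sustainable-use and internal
    unit value indices, and the capability aggregation yielding Total
    Ecosystem Capability and the ecological debt or credit between two
    accounting dates. Includes a seeded synthetic-landscape generator so
    every account is testable against known ground truth, and ships the
    published Mahavavy-Kinkony Complex (Madagascar, 2013-2018) account
    tables as worked-example data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
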