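Package: nomenreg
Title: Automated Pre-Publication Registration of Nomenclatural Acts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a publisher-side, machine-to-machine workflow for
    registering nomenclatural acts (new taxa, new combinations, replacement
    names, typifications) with taxonomic name registries such as IPNI,
    Index Fungorum, MycoBank and ZooBank. Parses taxonomic treatments from
    TaxPub-flavoured JATS XML, classifies acts and validates them against a
    per-registry registrability matrix, mints registry identifiers, keeps
    records embargoed until the publication date, injects identifiers back
    into the manuscript XML, exports name records in a Taxon Concept
    Transfer Schema (TCS) subset, and ships a seeded synthetic-manuscript
    generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    stringi,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
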