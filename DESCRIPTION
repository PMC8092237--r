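Package: bhsgrna
Title: Design and Evaluation of Bubble-Hairpin Guide RNAs for Base Editors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering single guide RNAs (sgRNAs) whose 5' end
    folds back on the spacer to form a hairpin with a deliberate internal
    bubble opposite the base-editing window ("bubble-hairpin" or BH-sgRNAs),
    a design that suppresses guide-dependent off-target deamination by
    cytosine and adenine base editors. Provides deterministic construction
    of hairpin and bubble-hairpin guides over the hairpin-length /
    bubble-size / bubble-position parameter space, secondary-structure
    validation by base-pair maximization, quantification of editing outcomes
    (per-position conversion, window-level editing, indels, by-products)
    from amplicon sequencing reads, mismatch-based off-target site
    enumeration with guide-dependent SNV classification, and synthetic-data
    generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
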