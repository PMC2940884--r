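Package: phytopsi
Title: Phytomics Similarity Index for Batch-to-Batch Quality Control of
    Botanical Extracts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the batch-to-batch consistency of complex
    botanical extracts from LC/MS chemical fingerprints and gene-expression
    bioresponse fingerprints. Implements the Phytomics Similarity Index
    (PSI), a ratio-matrix pattern statistic that correlates, feature by
    feature, the full set of pairwise intensity ratios of two fingerprints,
    together with the conventional correlation R, slope-based feature
    weights, and outlier-feature detection. Includes fingerprint peak
    selection from replicate injections (relative-intensity, reproducibility
    and linearity rules), peak matching by m/z and retention time, total
    ion current coverage, fold-change filtering of gene panels, seeded
    synthetic-data generators for validation scenarios, delimited-text
    readers and writers, batch comparison reports, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, optparse
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
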