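Package: phagoscreen
Title: Analysis of FACS-Sorted Pooled CRISPR Knockout Screens with
    Protein-Complex Annotation of Hits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooled CRISPR knockout screens read out by
    fluorescence-activated cell sorting, such as phagocytosis reporter
    screens. Counts sgRNA cassettes from sequencing reads against a guide
    library index, tests per-guide differential abundance between sorted
    fractions with a negative-binomial Wald test (median-of-ratios
    normalization, method-of-moments dispersion estimation with trend
    shrinkage), aggregates ranked guides to gene-level enrichment scores
    with permutation p-values, and calls depleted or enriched genes.
    Hit lists can be projected onto protein-protein interaction data to
    build hit subnetworks annotated with protein-complex membership and
    completeness, and tested for gene-set over-representation with
    Fisher's exact test. A synthetic-data generator with planted effects
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
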