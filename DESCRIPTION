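Package: refstab
Title: Reference Gene Stability Analysis for RT-qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for selecting and validating RT-qPCR reference genes
    from quantification-cycle (Cq) data. Implements four stability
    algorithms (geNorm pairwise variation, the comparative deltaCt
    method, the BestKeeper index correlation, and the NormFinder
    model-based variance decomposition in ungrouped and grouped modes),
    an integrated consensus ranking by per-gene geometric mean,
    normalisation-factor construction and validation via summed
    per-timepoint coefficients of variation, and a QC screen for cDNA
    synthesis batches with failed random priming. A synthetic Cq data
    generator emulating a developmental time-course study design (whole
    embryos, heads and forelimbs across gestational ages) provides
    ground-truth datasets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
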