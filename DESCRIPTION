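Package: rootscreen
Title: Root-Trait Screening of Crop Genotypes Under Drought and Low-Phosphorus Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for large-scale root-system-architecture screening trials of
    crop genotypes grown under control, low-phosphorus, osmotic-drought and
    combined stress. Derives global and depth-resolved root traits from
    per-plant measurements, computes stress-tolerance indices (SSI, TI, SI,
    HMI, MPI, GMPI, STI) and their summed stress-tolerance score, estimates
    broad-sense heritability from expected mean squares, quantifies treatment
    effects as log response ratios with sampling variances and pooled
    confidence intervals, and groups genotypes by correlation, principal
    component and hierarchical cluster analysis. Includes a log-normal
    genotype-by-treatment trial simulator for method validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    metafor,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
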