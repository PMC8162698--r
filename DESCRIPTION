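Package: kroncrc
Title: Kronecker-Structured Dynamical Models of Multi-Pathway Colorectal
    Carcinogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Linear dynamical-system models of colorectal carcinogenesis at
    the crypt level. Per-gene mutation graphs (point mutation and loss of
    heterozygosity over the statuses wild-type, m, l, mm, ml, ll) are
    combined via Kronecker sums into a genotype-level rate matrix;
    mutational dependencies such as accelerated APC and KRAS mutation after
    mismatch-repair deficiency enter as additive Kronecker-product
    components with selector diagonals. The dynamics are solved exactly by
    the matrix exponential, with a factorized fast path for the
    independent-mutation model. Scenario presets cover Lynch syndrome
    (MLH1/MSH2, point-mutation or LOH germline variant), Lynch-like and
    sporadic MSI, microsatellite-stable carcinogenesis, and familial
    adenomatous polyposis, together with aggregation queries over genotype
    classes (MMR-deficient foci, adenomatous and cancerous states) and
    pathway-proportion reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    withr,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
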