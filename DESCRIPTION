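Package: mitomixr
Title: Mitogenome Population Distances, Shared Haplogroup Distance and
    Admixture Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Population-genetic analysis of complete mitochondrial genomes:
    IUPAC-ambiguity-aware global alignment of mitogenomes against a
    reference with affine gap costs, reference-coordinate variant calling,
    indel-to-SNP recoding with mutational hotspot exclusion, Tamura-Nei
    (1993) gamma-corrected distances, AMOVA-based pairwise Fst with
    permutation testing, Slatkin linearization and classical
    multidimensional scaling, the Shared Haplogroup Distance (SHD) between
    sub-haplogroup frequency profiles, and the MITOMIX exhaustive admixture
    search that decomposes a test population into convex combinations of
    candidate source populations.  A forward simulator generates haplogroup
    hierarchies, population profiles and per-sample mitogenomes so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
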