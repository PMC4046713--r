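Package: poolsnv
Title: Somatic SNV Validation and Variant Detection in Non-Indexed Pooled
    Tumor Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Validates candidate somatic single-nucleotide variants from
    paired tumor/normal deep targeted-sequencing allele counts, detects
    known somatic SNVs in non-indexed DNA pools of up to ten samples,
    calls novel single-sample variants in pools through an
    expected-allele-fraction filter cascade with replicate concordance,
    and evaluates the procedure (confusion matrices, false discovery
    rate, median-ratio pool skew, coverage-evenness and allele-fraction
    concordance statistics) on a synthetic pooled-tumor count generator
    with subclonal allele-fraction structure, germline SNPs, imperfect
    pool mixing and material-dependent coverage dispersion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
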