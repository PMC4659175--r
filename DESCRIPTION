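Package: snpbeta
Title: Simulating and Diagnosing SNP Artifacts in Infinium Methylation
    Array Beta Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of Illumina Infinium I/II probe
    chemistry at CpG sites carrying genomic SNPs, and tools to diagnose
    the resulting artifacts in methylation readouts. Models bisulfite
    conversion, probe design, allele-specific hybridization and
    single-base extension; generates synthetic two-population cohorts
    with Hardy-Weinberg genotypes and known methylation truth; runs a
    beta/M-value differential-methylation pipeline (Student's t-test,
    Benjamini-Hochberg FDR, detection filtering, neighbor-probe scan);
    classifies per-probe distributions of individual beta values into
    tri-modal, bi-modal, flattened and cloud-like patterns driven by
    genotype rather than methylation; and annotates SNPs with allele
    frequency differences and Hudson's Fst.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
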