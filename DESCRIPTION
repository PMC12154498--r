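Package: kaspanel
Title: KASP Marker Panels, SNP Fingerprinting and Core Germplasm Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds SNP fingerprinting systems for crop germplasm based on
    KASP (Kompetitive Allele-Specific PCR) markers: candidate-SNP screening
    from VCF call sets (hard filters, site filters, flank isolation,
    mid-frequency windows, even genome-wide selection), KASP assay design
    under primer constraints, marker diversity statistics (MAF, gene
    diversity, heterozygosity, PIC), genetic distance matrices (Nei 1983 DA,
    modified Rogers, Cavalli-Sforza-Edwards) and neighbor-joining trees,
    maximum-likelihood admixture analysis with Evanno delta-K model
    selection, genotype PCA, minimal discriminating-marker selection by
    greedy set cover with an exact oracle, core-collection optimization, and
    fingerprint barcode encoding. Includes a synthetic-data generator for
    admixed diploid panels and toy VCFs so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    vcfR,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
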