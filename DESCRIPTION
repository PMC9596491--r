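Package: sexscan
Title: Sex Chromosome Identification from Population Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies X- and Y-linked SNPs and pseudoautosomal region
    boundaries in male-heterogametic (XY) species from multi-sample
    genotype and depth data. Implements a per-SNP Fisher exact sex GWAS
    with Bonferroni control, male/female sequencing-depth ratios with
    interquartile-range outlier calling, relative male heterozygosity,
    sliding-window depth summaries, and threshold-based segmentation of
    a sex scaffold into PAR1/HRX/PAR2. Includes a population simulator
    with X-hemizygous depth and gametolog heterozygosity for validation,
    CpG-corrected Kimura 2-parameter repeat divergence landscapes with
    cross-genome recent-insertion comparison, and karyotype-to-scaffold
    size concordance via area-fraction estimates and linear regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
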