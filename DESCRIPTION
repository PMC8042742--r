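Package: dupincompat
Title: Detection of Genetic Incompatibilities from Duplicated Genes in
    Multiparent RIL Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect Bateson-Dobzhansky-Muller incompatibilities caused
    by reciprocally pseudofunctionalized duplicated genes. Simulates multiparent
    recombinant inbred line (RIL) subpopulations under a diallel crossing design
    with configurable lethal incompatibilities and modifier rescue, reconstructs
    founder-haplotype mosaics from noisy biallelic markers with a hidden Markov
    model, scans unlinked duplicated gene pairs for segregation distortion of
    founder allele-pair combinations with chi-square tests per subpopulation and
    population-wide, calls gene copies functional or nonfunctional from
    loss-of-function variant effects, promoter-methylation clustering,
    pseudoheterozygous variant assignment and coverage, maps rescuing modifier
    copies by mixed-model genome-wide association with kinship correction, and
    estimates gene copy number from read-depth ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
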