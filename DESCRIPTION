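Package: poolsweep
Title: Selective Sweep Scans for Two-Population Pool-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome scans for selective sweeps from pooled whole-genome
    sequencing (pool-seq) of two populations. Reads Popoolation2 sync tables
    and VCF allelic depths, applies standard SNP quality filters (minor
    allele frequency, depth, site quality, proximity to indels), and computes
    three window statistics over non-overlapping 25-kb windows: the
    two-population Weir-Cockerham fixation index F_ST, pooled heterozygosity
    H_p with its negative Z-transform (-ZH_p), and a cross-population
    composite likelihood ratio (XP-CLR) score. Windows in the top percentile
    of all three distributions are intersected into candidate sweep regions
    and annotated with overlapping genes from a GFF3 file. A synthetic
    pool-seq generator (Balding-Nichols population split plus a star-like
    genetic hitchhiking model) provides data with known planted sweeps for
    validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    tools,
    pracma,
    ape,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
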