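Package: triofunnel
Title: Trio Whole-Genome Variant Prioritization with Network Propagation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Variant-prioritization funnel for proband-mother-father trio
    whole-genome sequencing. Reads an annotated multi-sample VCF, applies
    site-quality hard filters, partitions variants by Mendelian inheritance
    mode (X-linked, autosomal recessive, de novo), selects functionally
    important consequences and rare alleles against population panels, and
    prioritizes candidate genes along two parallel workflows: proximity to a
    disease seed-gene set on a weighted interaction network (direct-neighbor
    summation and Gaussian-smoothing diffusion) and pathogenicity-score
    ranking (SIFT/PolyPhen-2). Candidates are merged, manually curated genes
    excluded, and finalists resolved against orthogonal zygosity genotyping.
    Ships a seeded simulator for Mendelian-consistent trio genotypes and
    scale-free weighted networks with a planted causal variant, so the whole
    funnel is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
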