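Package: phagestate
Title: Lytic-Lysogenic State Inference from Phage Metatranscriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the dominant infection state (lytic versus lysogenic) of a
    temperate cyanophage infecting Microcystis from metatranscriptomic data.
    Provides filtered competitive read-pair quantification over phage and host
    gene models, library-size and host rpoB normalisation, a marker-gene
    log2-ratio state classifier (tail sheath gp091 versus IS607 transposase
    gp135 / recombinase gp136), whole-genome co-expression clustering with a
    permutation test that collapses statistically indistinguishable branches,
    Bray-Curtis non-metric multidimensional scaling, environmental vector
    fitting, and exhaustive BIOENV/BEST environmental subset selection. A
    synthetic-data module generates gene models, environmental tables, latent
    infection states, negative-binomial count matrices and paired-end SAM
    fixtures with known ground truth so the whole pipeline is testable
    without any sequencing download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vegan,
    ape,
    yaml,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
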