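Package: phageflux
Title: Recombination, Genetic Flux and Pan-Genome Analysis of Phage Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-level analysis of homologous recombination in aligned phage
    (prophage) genome collections. At the genome level, a haplotype-copying
    hidden Markov model paints each genome as a mosaic of chunks copied from
    donor genomes, accumulates a co-ancestry matrix, clusters individuals with
    a Dirichlet-multinomial partition MCMC and a greedy merge tree, and
    quantifies directional genetic flux between populations with Wilcoxon
    rank-sum comparisons. At the gene level, an identity-threshold pan-genome
    classifier assigns gene families to core, soft-core, shell and singleton
    categories, the Hudson-Kaplan four-gamete bound counts minimum
    recombination events per gene, and a diversity-controlled regression
    scores per-gene recombination intensity. A synthetic-data module with
    planted population structure, migration and recombination makes every
    stage verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
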