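#' Metadata for the published H. pylori prophage genome collection
#'
#' Thirty complete prophage genomes (>20 kb): one *Helicobacter acinonychis*
#' prophage (Hac) and twenty-nine *H. pylori* prophages with their phage
#' population assignments and genome lengths. Three members are known
#' problem cases for alignment-based painting: UK-EN32-U is identical to
#' UK-EN31-U, Fr-MEG235-U is identical to Fr-ANT170-U, and Pt-4481-G
#' carries a large inversion whose region does not align.
#'
#' @return data.frame with columns `genome`, `phage_population`,
#'   `genome_length_bp`.
#' @export
prophage_genome_table <- function() {
  utils::read.delim(system.file("extdata", "prophage_genomes.tsv",
                                package = "phageflux"),
                    stringsAsFactors = FALSE)
}

#' Synthetic alignment standing in for the prophage genome collection
#'
#' Builds a seeded random nucleotide alignment with one record per genome in
#' [prophage_genome_table()], planting the two documented byte-identical
#' pairs (UK-EN32-U := UK-EN31-U, Fr-MEG235-U := Fr-ANT170-U) so that the
#' duplicate-removal filter reproduces the published retained-genome count
#' without the real sequences. The sequences themselves are synthetic; only
#' the genome list and the identity structure are real.
#'
#' @param seed integer.
#' @param length alignment length in columns.
#' @return a `haplotype_alignment` with population labels.
#' @export
synthetic_prophage_alignment <- function(seed = 1L, length = 500L) {
  tab <- prophage_genome_table()
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(nrow(tab)), function(i) rand_dna(length), "")
  })
  names(seqs) <- tab$genome
  seqs["UK-EN32-U"] <- seqs["UK-EN31-U"]
  seqs["Fr-MEG235-U"] <- seqs["Fr-ANT170-U"]
  haplotype_alignment(seqs, alphabet = "nt",
                      labels = stats::setNames(tab$phage_population,
                                               tab$genome))
}
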