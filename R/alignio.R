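#' Aligned haplotypes with sample metadata
#'
#' Container for a gap-aware multiple alignment: one residue string per
#' sample, all the same length, plus an optional population label per sample.
#' This is the unit every downstream stage (core-SNP extraction, painting,
#' gene-level statistics) consumes.
#'
#' @param sequences named character vector of aligned sequences (names are
#'   sample ids). All strings must have identical nchar.
#' @param alphabet `"nt"` (A, C, G, T plus `-` gap and N ambiguity) or
#'   `"aa"` (the 20 amino acids plus `-`, `X`, `*`).
#' @param labels optional named character vector mapping sample id to
#'   population label; names must be a subset of the sample ids.
#'
#' @return An object of class `haplotype_alignment`: a list with elements
#'   `sequences` (named, upper-cased character vector), `length` (alignment
#'   columns), `alphabet`, and `labels` (named character vector or `NULL`).
#' @export
haplotype_alignment <- function(sequences, alphabet = c("nt", "aa"),
                                labels = NULL) {
  alphabet <- match.arg(alphabet)
  if (length(sequences) == 0L) {
    stop("empty alignment: no sequences supplied", call. = FALSE)
  }
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("all sequences must be named with sample ids", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths differ (",
         paste(range(lens), collapse = "-"), ")", call. = FALSE)
  }
  allowed <- if (alphabet == "nt") "ACGTN-" else "ACDEFGHIKLMNPQRSTVWYX*-"
  bad <- grepl(sprintf("[^%s]", allowed), sequences)
  if (any(bad)) {
    stop("sequence(s) contain residues outside the ", alphabet, " alphabet: ",
         paste(utils::head(ids[bad], 3L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- labels[names(labels) %in% ids]
    if (length(labels) == 0L) labels <- NULL
  }
  structure(
    list(sequences = sequences, length = unname(lens[1L]),
         alphabet = alphabet, labels = labels),
    class = "haplotype_alignment"
  )
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("haplotype_alignment: %d sequences x %d columns (%s)\n",
              length(x$sequences), x$length, x$alphabet))
  if (!is.null(x$labels)) {
    cat("populations:",
        paste(names(table(x$labels)), table(x$labels), sep = ":",
              collapse = " "), "\n")
  }
  invisible(x)
}

n_samples <- function(aln) length(aln$sequences)
sample_ids <- function(aln) names(aln$sequences)

#' Character matrix view of an alignment (samples x columns)
#' @keywords internal
#' @noRd
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  rownames(m) <- sample_ids(aln)
  m
}

#' Read a multi-FASTA alignment
#'
#' Reads an aligned multi-FASTA file (all records must have equal length) and
#' returns a validated [haplotype_alignment()]. Residues are upper-cased.
#'
#' @param path path to a FASTA file.
#' @inheritParams haplotype_alignment
#' @return A `haplotype_alignment`.
#' @export
read_alignment <- function(path, alphabet = c("nt", "aa"), labels = NULL) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- as.character(set)
  # FASTA headers may carry descriptions after whitespace; the id is field 1
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1L)
  haplotype_alignment(seqs, alphabet = alphabet, labels = labels)
}

#' Write an alignment as multi-FASTA
#'
#' @param aln a `haplotype_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(aln$sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a two-column sample/population label table
#'
#' @param path TSV with columns `sample` and `population` (header required).
#' @return named character vector (names = sample ids).
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(tab))) {
    stop("label table must have 'sample' and 'population' columns",
         call. = FALSE)
  }
  stats::setNames(as.character(tab$population), as.character(tab$sample))
}

#' Apply genome exclusion filters
#'
#' Removes explicitly named genomes (e.g. a genome whose inverted region does
#' not align) and, optionally, any genome whose aligned sequence is
#' byte-identical to an earlier retained genome. Every removal is recorded
#' with its reason in the `removals` attribute; a painting analysis cannot
#' tolerate duplicated haplotypes or unalignable regions, hence this filter
#' runs before SNP extraction.
#'
#' @param aln a `haplotype_alignment`.
#' @param drop_duplicates if `TRUE`, drop genomes identical to an earlier one.
#' @param drop_ids character vector of sample ids to remove explicitly.
#' @return The filtered `haplotype_alignment`, with attribute `removals`
#'   (data.frame: `sample`, `reason`).
#' @export
apply_exclusions <- function(aln, drop_duplicates = TRUE,
                             drop_ids = character()) {
  ids <- sample_ids(aln)
  unknown <- setdiff(drop_ids, ids)
  if (length(unknown) > 0L) {
    stop("drop_ids not present in alignment: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  removals <- data.frame(sample = character(), reason = character(),
                         stringsAsFactors = FALSE)
  keep <- !(ids %in% drop_ids)
  if (any(!keep)) {
    removals <- rbind(removals, data.frame(
      sample = ids[!keep], reason = "explicitly excluded",
      stringsAsFactors = FALSE))
  }
  seqs <- aln$sequences[keep]
  if (isTRUE(drop_duplicates) && length(seqs) > 1L) {
    dup <- duplicated(seqs)
    if (any(dup)) {
      first_of <- names(seqs)[match(seqs[dup], seqs)]
      removals <- rbind(removals, data.frame(
        sample = names(seqs)[dup],
        reason = paste0("identical to ", first_of),
        stringsAsFactors = FALSE))
      seqs <- seqs[!dup]
    }
  }
  out <- haplotype_alignment(seqs, alphabet = aln$alphabet,
                             labels = aln$labels)
  attr(out, "removals") <- removals
  out
}

#' Write an exclusion log
#'
#' @param aln result of [apply_exclusions()].
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_removal_log <- function(aln, path) {
  rem <- attr(aln, "removals")
  lines <- if (is.null(rem) || nrow(rem) == 0L) {
    "no genomes removed"
  } else {
    sprintf("removed %s: %s", rem$sample, rem$reason)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Extract core SNPs from a nucleotide alignment
#'
#' Retains alignment columns that are polymorphic, strictly biallelic, and
#' free of gaps and ambiguity codes in every sample (the copying model below
#' assumes complete two-allele data at every site). Alleles are coded 0/1
#' with 0 the major allele; a 50/50 tie is broken towards the alphabetically
#' first allele.
#'
#' @param aln a nucleotide `haplotype_alignment` with at least 2 samples.
#' @return An object of class `snp_haplotypes`: list with `matrix`
#'   (N x L integer 0/1, rownames = sample ids), `positions` (0-based,
#'   strictly increasing alignment column indices), `distances`
#'   (`diff(positions)`), and `labels` carried over from `aln`.
#' @export
extract_core_snps <- function(aln) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  if (aln$alphabet != "nt") stop("core SNPs require a nucleotide alignment",
                                 call. = FALSE)
  if (n_samples(aln) < 2L) stop("need at least 2 samples", call. = FALSE)
  m <- aln_matrix(aln)
  ok <- logical(ncol(m))
  allele0 <- character(ncol(m))
  allele1 <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(col == "-" | col == "N")) next
    tab <- table(col)
    if (length(tab) != 2L) next
    # major allele coded 0; tie -> alphabetically first (names(tab) sorted)
    ord <- order(-as.integer(tab), names(tab))
    ok[j] <- TRUE
    allele0[j] <- names(tab)[ord[1L]]
    allele1[j] <- names(tab)[ord[2L]]
  }
  pos <- which(ok)
  if (length(pos) == 0L) {
    warning("no core SNP columns found", call. = FALSE)
    mat <- matrix(integer(), nrow = n_samples(aln), ncol = 0L,
                  dimnames = list(sample_ids(aln), NULL))
    return(structure(list(matrix = mat, positions = integer(),
                          distances = integer(), labels = aln$labels),
                     class = "snp_haplotypes"))
  }
  mat <- matrix(0L, nrow = n_samples(aln), ncol = length(pos),
                dimnames = list(sample_ids(aln), NULL))
  for (k in seq_along(pos)) {
    mat[, k] <- as.integer(m[, pos[k]] == allele1[pos[k]])
  }
  structure(
    list(matrix = mat, positions = pos - 1L,        # 0-based
         distances = diff(pos), labels = aln$labels),
    class = "snp_haplotypes"
  )
}

#' @export
print.snp_haplotypes <- function(x, ...) {
  cat(sprintf("snp_haplotypes: %d samples x %d biallelic SNPs\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Write a SNP matrix and its positions
#'
#' Emits a samples x positions TSV of 0/1 codes plus a one-column positions
#' file (0-based alignment coordinates).
#'
#' @param snps a `snp_haplotypes`.
#' @param path output TSV path; positions go to `paste0(path, ".positions")`.
#' @return `path`, invisibly.
#' @export
write_snp_tsv <- function(snps, path) {
  df <- as.data.frame(snps$matrix)
  names(df) <- snps$positions
  utils::write.table(cbind(sample = rownames(snps$matrix), df), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(as.character(snps$positions), paste0(path, ".positions"))
  invisible(path)
}

#' Nucleotide diversity of a gene alignment
#'
#' Removes every column containing a gap (complete deletion), then computes
#' pi as the mean, over all unordered sample pairs, of the per-site pairwise
#' difference count divided by the gap-filtered length L. Ambiguity symbols
#' (N) are treated as mismatching nothing: columns containing N are also
#' removed, so pi is computed on fully resolved sites only.
#'
#' @param aln a nucleotide `haplotype_alignment`, N >= 2.
#' @return list with `pi` (per-site diversity), `L` (gap-filtered length) and
#'   `S` (segregating sites among the retained columns).
#' @export
nucleotide_diversity <- function(aln) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  if (n_samples(aln) < 2L) stop("need at least 2 samples", call. = FALSE)
  m <- gap_filter(aln_matrix(aln))
  L <- ncol(m)
  if (L == 0L) stop("alignment has no gap-free columns", call. = FALSE)
  n <- nrow(m)
  S <- sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
  diffs <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      diffs <- diffs + sum(m[i, ] != m[j, ])
    }
  }
  n_pairs <- n * (n - 1) / 2
  list(pi = diffs / (n_pairs * L), L = L, S = S)
}

# drop columns containing gaps or ambiguity symbols (complete deletion)
gap_filter <- function(m, drop = c("-", "N")) {
  keep <- !apply(m, 2L, function(col) any(col %in% drop))
  m[, keep, drop = FALSE]
}
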