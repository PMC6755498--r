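#' A predicted gene (protein product) from one genome
#'
#' @param genome_id,gene_id identifiers; the pair must be unique within a
#'   gene set.
#' @param sequence non-empty amino-acid residue string.
#' @param cds optional nucleotide CDS string (used by
#'   [detect_interrupted()]).
#' @return list of class `gene_record`.
#' @export
gene_record <- function(genome_id, gene_id, sequence, cds = NULL) {
  if (!nzchar(sequence)) stop("empty gene sequence", call. = FALSE)
  structure(list(genome_id = genome_id, gene_id = gene_id,
                 sequence = toupper(sequence), cds = cds),
            class = "gene_record")
}

#' Percent identity of the best local alignment, shorter-length normalized
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps (opening
#' 10, extension 4 by default); the score is
#' `100 * identical aligned positions / nchar(shorter sequence)`, the
#' shorter-length convention used by blastp-style pan-genome pipelines.
#' Symmetric in its arguments.
#'
#' @param a,b `gene_record`s (or bare amino-acid strings).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(a, b, gap_opening = 10, gap_extension = 4) {
  sa <- if (inherits(a, "gene_record")) a$sequence else toupper(a)
  sb <- if (inherits(b, "gene_record")) b$sequence else toupper(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence", call. = FALSE)
  if (identical(sa, sb)) return(100)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb), type = "local",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  100 * Biostrings::nmatch(aln) / min(nchar(sa), nchar(sb))
}

#' Identity-threshold clustering of genes into a pan-genome
#'
#' Builds a graph with an edge between two genes whenever their
#' shorter-length percent identity reaches `threshold`; clusters are the
#' connected components. With `split_paralogs = TRUE`, any cluster holding
#' two or more genes from the same genome is re-clustered by single linkage
#' at a stricter threshold (`threshold + 10`, capped at 95) so that
#' same-genome fragments (typically interrupted genes rather than true
#' duplications) can separate. Category rules: core = present in 100 % of
#' genomes, soft-core = present in at least 90 % (but not all), singleton =
#' present in exactly one genome, shell = the rest.
#'
#' @param genes list of `gene_record`s.
#' @param threshold percent identity in \[1, 100\].
#' @param split_paralogs logical.
#' @param genomes optional character vector of all genome ids (so genomes
#'   contributing no gene still count in presence fractions).
#' @return object of class `pan_genome`: list with `clusters` (list of
#'   gene-id vectors), `presence` (clusters x genomes logical matrix),
#'   `categories` (character vector per cluster), `config`.
#' @export
cluster_genes <- function(genes, threshold, split_paralogs = FALSE,
                          genomes = NULL) {
  if (threshold < 1 || threshold > 100) {
    stop("threshold must lie in [1, 100]", call. = FALSE)
  }
  if (length(genes) == 0L) {
    return(structure(list(clusters = list(),
                          presence = matrix(FALSE, 0, 0),
                          categories = character(),
                          config = list(threshold = threshold,
                                        split_paralogs = split_paralogs)),
                     class = "pan_genome"))
  }
  key <- vapply(genes, function(g) paste(g$genome_id, g$gene_id, sep = "::"),
                "")
  if (anyDuplicated(key)) stop("duplicate (genome_id, gene_id)",
                               call. = FALSE)
  genome_of <- vapply(genes, function(g) g$genome_id, "")
  if (is.null(genomes)) genomes <- sort(unique(genome_of))
  n <- length(genes)
  # pairwise identity matrix (order-independent clustering)
  idm <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        idm[i, j] <- idm[j, i] <- pairwise_identity(genes[[i]], genes[[j]])
      }
    }
  }
  comp <- components_at(idm, threshold)
  if (isTRUE(split_paralogs)) {
    strict <- min(threshold + 10, 95)
    out <- integer(n)
    nxt <- 0L
    for (cl in sort(unique(comp))) {
      members <- which(comp == cl)
      if (anyDuplicated(genome_of[members])) {
        sub <- components_at(idm[members, members, drop = FALSE], strict)
        for (s in sort(unique(sub))) {
          nxt <- nxt + 1L
          out[members[sub == s]] <- nxt
        }
      } else {
        nxt <- nxt + 1L
        out[members] <- nxt
      }
    }
    comp <- out
  }
  clusters <- split(key, comp)
  # deterministic cluster order: by first member's input position
  ord <- order(vapply(split(seq_len(n), comp), min, 0L))
  clusters <- lapply(unname(clusters[ord]), unname)
  presence <- t(vapply(split(genome_of, comp)[ord], function(gs) {
    genomes %in% gs
  }, logical(length(genomes))))
  if (length(genomes) == 1L) presence <- matrix(presence, ncol = 1L)
  colnames(presence) <- genomes
  rownames(presence) <- paste0("cluster_", seq_along(clusters))
  categories <- classify_clusters(presence)
  structure(list(clusters = clusters, presence = presence,
                 categories = categories,
                 config = list(threshold = threshold,
                               split_paralogs = split_paralogs)),
            class = "pan_genome")
}

# connected components of the >= threshold identity graph
components_at <- function(idm, threshold) {
  n <- nrow(idm)
  if (n == 1L) return(1L)
  g <- igraph::graph_from_adjacency_matrix(idm >= threshold, mode = "max",
                                           diag = FALSE)
  igraph::components(g)$membership
}

classify_clusters <- function(presence) {
  n_genomes <- ncol(presence)
  frac <- rowSums(presence) / n_genomes
  ifelse(rowSums(presence) == 1L, "singleton",
         ifelse(frac == 1, "core",
                ifelse(frac >= 0.9, "soft_core", "shell")))
}

#' @export
print.pan_genome <- function(x, ...) {
  counts <- table(factor(x$categories,
                         c("core", "soft_core", "shell", "singleton")))
  cat(sprintf(
    "pan_genome: %d clusters at i=%g (split=%s): %d core, %d soft-core, %d shell, %d singleton\n",
    length(x$clusters), x$config$threshold, x$config$split_paralogs,
    counts["core"], counts["soft_core"], counts["shell"],
    counts["singleton"]))
  invisible(x)
}

#' Pan-genome parameter sweep
#'
#' Clusters the same gene set at identity thresholds 40-90 with and without
#' paralogue splitting and tabulates the pan-genome size and category
#' counts; higher thresholds can only refine clusters, so the pan size is
#' non-decreasing in the threshold at a fixed split flag.
#'
#' @param genes list of `gene_record`s.
#' @param thresholds identity thresholds to sweep.
#' @param genomes optional full genome id set.
#' @return data.frame with one row per (threshold, split) combination:
#'   `identity`, `split`, `pan_size`, `core`, `soft_core`, `shell`,
#'   `singleton`.
#' @export
pangenome_sweep <- function(genes, thresholds = c(40, 50, 60, 70, 80, 90),
                            genomes = NULL) {
  grid <- expand.grid(identity = thresholds, split = c(FALSE, TRUE))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pg <- cluster_genes(genes, grid$identity[i], grid$split[i],
                        genomes = genomes)
    counts <- table(factor(pg$categories,
                           c("core", "soft_core", "shell", "singleton")))
    data.frame(identity = grid$identity[i], split = grid$split[i],
               pan_size = length(pg$clusters),
               core = as.integer(counts["core"]),
               soft_core = as.integer(counts["soft_core"]),
               shell = as.integer(counts["shell"]),
               singleton = as.integer(counts["singleton"]))
  })
  do.call(rbind, rows)
}

#' Flag same-genome cluster co-members that are fragments of one gene
#'
#' In phage annotation, an internal stop codon followed by a restart is
#' frequently annotated as two genes; in a cluster these masquerade as
#' paralogues. A same-genome pair is flagged "interrupted" when the
#' concatenation of the two fragments aligns end-to-end to a full-length
#' cluster member from another genome (identity of the concatenation against
#' the full-length member at least `min_identity` over at least
#' `min_coverage` of its length). Genuinely duplicated divergent copies do
#' not satisfy the concatenation geometry and are left unflagged. Requires
#' nucleotide CDS on the records to confirm the internal-stop artifact;
#' without any CDS the check is skipped with a message.
#'
#' @param genes list of `gene_record`s (with `cds` where available).
#' @param pg a `pan_genome` over those genes.
#' @param min_identity,min_coverage acceptance thresholds for the
#'   concatenation match.
#' @return data.frame with columns `cluster`, `genome_id`, `gene_a`,
#'   `gene_b`, `matched_member`, `identity`, `coverage`, `internal_stop`;
#'   zero rows when nothing is flagged.
#' @export
detect_interrupted <- function(genes, pg, min_identity = 80,
                               min_coverage = 0.8) {
  has_cds <- any(vapply(genes, function(g) !is.null(g$cds), TRUE))
  if (!has_cds) {
    message("no nucleotide CDS supplied; interrupted-gene check skipped")
    return(invisible(NULL))
  }
  key <- vapply(genes, function(g) paste(g$genome_id, g$gene_id, sep = "::"),
                "")
  names(genes) <- key
  out <- list()
  for (ci in seq_along(pg$clusters)) {
    members <- pg$clusters[[ci]]
    gs <- genes[members]
    genome_of <- vapply(gs, function(g) g$genome_id, "")
    dup_genomes <- unique(genome_of[duplicated(genome_of)])
    if (length(dup_genomes) == 0L) next
    for (gm in dup_genomes) {
      frag_keys <- members[genome_of == gm]
      if (length(frag_keys) != 2L) next       # only the two-fragment pattern
      full_keys <- members[genome_of != gm]
      if (length(full_keys) == 0L) next
      # reference: the longest member from another genome
      full_len <- vapply(genes[full_keys], function(g) nchar(g$sequence), 0L)
      ref <- genes[[full_keys[which.max(full_len)]]]
      f1 <- genes[[frag_keys[1L]]]; f2 <- genes[[frag_keys[2L]]]
      best <- NULL
      for (cat_seq in c(paste0(f1$sequence, f2$sequence),
                        paste0(f2$sequence, f1$sequence))) {
        ident <- pairwise_identity(cat_seq, ref$sequence)
        cover <- min(nchar(cat_seq), nchar(ref$sequence)) /
          nchar(ref$sequence)
        if (is.null(best) || ident > best$ident) {
          best <- list(ident = ident, cover = cover)
        }
      }
      if (best$ident >= min_identity && best$cover >= min_coverage) {
        # the artifact signature: rejoining the fragment CDSs restores a
        # reading frame with a stop codon mid-gene
        stop_flag <- internal_stop(paste0(f1$cds, f2$cds)) ||
          internal_stop(paste0(f2$cds, f1$cds))
        out[[length(out) + 1L]] <- data.frame(
          cluster = ci, genome_id = gm,
          gene_a = frag_keys[1L], gene_b = frag_keys[2L],
          matched_member = paste(ref$genome_id, ref$gene_id, sep = "::"),
          identity = best$ident, coverage = best$cover,
          internal_stop = stop_flag, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(cluster = integer(), genome_id = character(),
                      gene_a = character(), gene_b = character(),
                      matched_member = character(), identity = numeric(),
                      coverage = numeric(), internal_stop = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# TRUE if a CDS carries a stop codon before its final codon
internal_stop <- function(cds) {
  if (is.null(cds) || !nzchar(cds) || nchar(cds) < 6) return(FALSE)
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3),
                      seq(3, nchar(cds), 3))
  any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA"))
}

#' Write pan-genome membership and presence/absence tables
#'
#' @param pg a `pan_genome`.
#' @param membership_path TSV of (cluster, gene) rows.
#' @param presence_path Rtab-style presence/absence TSV (clusters x
#'   genomes, 0/1).
#' @return invisibly, `membership_path`.
#' @export
write_pangenome <- function(pg, membership_path, presence_path = NULL) {
  mem <- do.call(rbind, lapply(seq_along(pg$clusters), function(i) {
    data.frame(cluster = rownames(pg$presence)[i],
               category = unname(pg$categories[i]),
               gene = unname(pg$clusters[[i]]), stringsAsFactors = FALSE)
  }))
  utils::write.table(mem, membership_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(presence_path)) {
    utils::write.table(
      cbind(cluster = rownames(pg$presence),
            as.data.frame(pg$presence * 1L)),
      presence_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(membership_path)
}
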