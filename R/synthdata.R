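#' Configuration for the mosaic population simulator
#'
#' The generator emulates K phage populations diverged from a common
#' ancestor, each individual genome a mosaic of founder-derived segments.
#' Segment lengths are geometric with mean `segment_mean`; each segment is
#' copied from the founder of a population drawn from the individual's row
#' of the migration matrix `M`, then per-site mutations are added. This
#' mosaic-copying model (not a full coalescent) matches the assumptions of
#' the copying HMM, so painting-based flux recovery is a clean
#' parameter-recovery exercise.
#'
#' @param n_pops number of populations K.
#' @param pop_sizes integer vector of length K.
#' @param genome_len genome length in bp.
#' @param divergence expected substitutions/site between the ancestor and
#'   each population founder.
#' @param migration K x K row-stochastic matrix; `M[a, b]` is the expected
#'   fraction of a population-a genome copied from the population-b
#'   founder. Default: identity (no migration).
#' @param mutation_rate per-site probability of a private mutation on top
#'   of the copied segment.
#' @param segment_mean mean mosaic segment length in bp.
#' @param seed integer; identical seeds give byte-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 2L, pop_sizes = rep(8L, n_pops),
                       genome_len = 20000L, divergence = 0.02,
                       migration = diag(n_pops), mutation_rate = 5e-4,
                       segment_mean = 2000L, seed = 1L) {
  stopifnot(n_pops >= 1L, length(pop_sizes) == n_pops,
            all(pop_sizes >= 1L), genome_len >= 1L,
            divergence >= 0, mutation_rate >= 0, segment_mean >= 1)
  migration <- as.matrix(migration)
  if (!all(dim(migration) == c(n_pops, n_pops)) ||
      any(migration < 0) ||
      any(abs(rowSums(migration) - 1) > 1e-9)) {
    stop("migration must be a K x K row-stochastic matrix", call. = FALSE)
  }
  if (divergence == 0 && mutation_rate == 0) {
    stop("no polymorphism possible: divergence and mutation_rate both 0",
         call. = FALSE)
  }
  structure(list(n_pops = as.integer(n_pops),
                 pop_sizes = as.integer(pop_sizes),
                 genome_len = as.integer(genome_len),
                 divergence = divergence, migration = migration,
                 mutation_rate = mutation_rate,
                 segment_mean = as.numeric(segment_mean),
                 seed = as.integer(seed)),
            class = "sim_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

mutate_sites <- function(chars, idx) {
  for (i in idx) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  chars
}

#' Simulate structured phage populations with planted migration
#'
#' See [sim_config()] for the generative model. Besides the alignment and
#' the true population labels, the generator returns two ground-truth flux
#' summaries: `migration` (the planted matrix M) and `expected_import`, the
#' realized pop x pop donor-attribution expectation. The latter accounts for
#' the fact that when several other individuals share the recipient's
#' founder at a site, a copying model can only attribute the site uniformly
#' among the matching donors - so it is the quantity a correct painting of
#' this data is expected to recover, computed here directly from the true
#' founder mosaics without any HMM.
#'
#' @param cfg a `sim_config`.
#' @return list with `alignment` (a gap-free `haplotype_alignment` with
#'   labels), `labels`, `migration`, `expected_import` (K x K: mean over
#'   recipients of each population of the expected donor-attribution
#'   fraction per donor population), and `ancestry` (N x L integer matrix
#'   of true founder origins).
#' @export
simulate_populations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    L <- cfg$genome_len
    K <- cfg$n_pops
    anc <- strsplit(rand_dna(L), "")[[1L]]
    founders <- lapply(seq_len(K), function(k) {
      n_mut <- stats::rbinom(1L, L, cfg$divergence)
      mutate_sites(anc, sample.int(L, n_mut))
    })
    pop_of <- rep(seq_len(K), cfg$pop_sizes)
    n <- length(pop_of)
    ids <- sprintf("pop%d_ind%d", pop_of,
                   unlist(lapply(cfg$pop_sizes, seq_len)))
    seqs <- character(n)
    ancestry <- matrix(0L, n, L)
    for (i in seq_len(n)) {
      chars <- character(L)
      origin <- integer(L)
      pos <- 1L
      while (pos <= L) {
        seg <- 1L + stats::rgeom(1L, 1 / cfg$segment_mean)
        end <- min(L, pos + seg - 1L)
        src <- sample.int(K, 1L, prob = cfg$migration[pop_of[i], ])
        chars[pos:end] <- founders[[src]][pos:end]
        origin[pos:end] <- src
        pos <- end + 1L
      }
      n_mut <- stats::rbinom(1L, L, cfg$mutation_rate)
      if (n_mut > 0L) chars <- mutate_sites(chars, sample.int(L, n_mut))
      seqs[i] <- paste(chars, collapse = "")
      ancestry[i, ] <- origin
    }
    names(seqs) <- ids
    labels <- stats::setNames(sprintf("pop%d", pop_of), ids)

    # realized donor-attribution expectation: at each site, recipient r's
    # founder matches the founders of some other individuals; attribute the
    # site uniformly among them, then average per recipient and pool by pop
    attr_pop <- matrix(0, n, K)
    for (r in seq_len(n)) {
      same <- t(ancestry[-r, , drop = FALSE]) == ancestry[r, ]  # L x (n-1)
      n_match <- rowSums(same)
      ok <- n_match > 0
      w <- same[ok, , drop = FALSE] / n_match[ok]
      donor_pop <- pop_of[-r]
      for (k in seq_len(K)) {
        attr_pop[r, k] <- sum(w[, donor_pop == k]) / sum(ok)
      }
    }
    expected_import <- matrix(0, K, K,
                              dimnames = list(sprintf("pop%d", 1:K),
                                              sprintf("pop%d", 1:K)))
    for (k in seq_len(K)) {
      expected_import[k, ] <- colMeans(attr_pop[pop_of == k, , drop = FALSE])
    }
  })
  aln <- haplotype_alignment(seqs, alphabet = "nt", labels = labels)
  list(alignment = aln, labels = labels, migration = cfg$migration,
       expected_import = expected_import, ancestry = ancestry)
}

#' Simulate a recombining gene alignment with planted crossovers
#'
#' Two divergent parental haplotypes; each recombinant picks a parent for
#' every block delimited by the `crossovers` planted breakpoint positions
#' (shared across haplotypes, as in a recombination hotspot). Private
#' mutations are added at unique, previously monomorphic sites
#' (infinite-sites style: singletons cannot create four-gamete
#' incompatibilities), so the minimum recombination bound can never exceed
#' the number of planted crossovers.
#'
#' @param n_haps number of haplotypes (>= 4 for informative output).
#' @param n_sites alignment length.
#' @param crossovers number of planted breakpoints (< n_sites).
#' @param seed integer.
#' @param parent_divergence per-site probability that the two parents
#'   differ.
#' @param private_rate expected private mutations per haplotype.
#' @return list with `alignment` (a `haplotype_alignment`) and
#'   `breakpoints` (0-based positions after which the parent may switch).
#' @export
simulate_recombining_gene <- function(n_haps, n_sites, crossovers, seed = 1L,
                                      parent_divergence = 0.3,
                                      private_rate = 1) {
  if (crossovers >= n_sites) stop("crossovers must be < n_sites",
                                  call. = FALSE)
  withr::with_seed(seed, {
    p1 <- strsplit(rand_dna(n_sites), "")[[1L]]
    p2 <- p1
    diff_idx <- which(stats::runif(n_sites) < parent_divergence)
    p2 <- mutate_sites(p2, diff_idx)
    bp <- if (crossovers > 0L) {
      sort(sample.int(n_sites - 1L, crossovers))
    } else integer()
    block <- findInterval(seq_len(n_sites) - 1L, bp) + 1L   # block per site
    seqs <- character(n_haps)
    # infinite sites: each private mutation hits a globally unused site
    # that is monomorphic in the parents, so it stays a singleton and can
    # never create a four-gamete pattern on its own
    mono_pool <- setdiff(seq_len(n_sites), diff_idx)
    for (h in seq_len(n_haps)) {
      par_of_block <- sample(1:2, crossovers + 1L, replace = TRUE)
      chars <- ifelse(par_of_block[block] == 1L, p1, p2)
      n_priv <- min(stats::rpois(1L, private_rate), length(mono_pool))
      if (n_priv > 0L) {
        idx <- sample(mono_pool, n_priv)
        mono_pool <- setdiff(mono_pool, idx)
        chars <- mutate_sites(chars, idx)
      }
      seqs[h] <- paste(chars, collapse = "")
    }
    names(seqs) <- sprintf("hap%d", seq_len(n_haps))
  })
  list(alignment = haplotype_alignment(seqs, alphabet = "nt"),
       breakpoints = bp)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# reverse-translate a protein with a fixed codon choice per amino acid
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

#' Simulate gene families for the pan-genome stage
#'
#' Each family starts from a random ancestral protein; every carrying
#' genome receives an independently mutated copy, with the per-copy
#' mutation fraction set so the expected pairwise identity between any two
#' copies equals the family's target identity. A family is
#' present in `round(presence_fraction * n_genomes)` genomes. With
#' `interrupted = TRUE`, one carrying genome's copy is emitted as a 5' and a
#' 3' fragment whose CDS carries an internal stop followed by a restart
#' codon - the annotation artifact that masquerades as a paralogue pair.
#'
#' @param n_genomes number of genomes.
#' @param families data.frame (or list of lists) with columns/fields
#'   `identity` (target percent identity), `presence` (fraction in (0, 1]),
#'   `interrupted` (logical).
#' @param seed integer.
#' @param length_aa ancestral protein length.
#' @return list with `genes` (list of `gene_record`s, CDS attached) and
#'   `truth` (data.frame: family, genomes carrying, interrupted genome or
#'   NA).
#' @export
simulate_gene_families <- function(n_genomes, families, seed = 1L,
                                   length_aa = 250L) {
  fam <- as.data.frame(families)
  stopifnot(all(fam$identity > 0), all(fam$identity <= 100),
            all(fam$presence > 0), all(fam$presence <= 1))
  genes <- list()
  truth <- list()
  withr::with_seed(seed, {
    for (f in seq_len(nrow(fam))) {
      anc <- sample(AA20, length_aa, replace = TRUE)
      n_carry <- max(1L, round(fam$presence[f] * n_genomes))
      carriers <- sample.int(n_genomes, n_carry)
      inter_genome <- NA_integer_
      if (isTRUE(fam$interrupted[f]) && n_carry >= 2L) {
        inter_genome <- carriers[1L]
      }
      # per-copy mutation fraction m chosen so the expected PAIRWISE
      # identity between two independently mutated copies hits the target:
      # matches ~ (1-m)^2 (re-substitution collisions are rare), so
      # m = 1 - sqrt(target)
      m_frac <- 1 - sqrt(fam$identity[f] / 100)
      for (g in carriers) {
        prot <- anc
        n_mut <- stats::rbinom(1L, length_aa, m_frac)
        if (n_mut > 0L) {
          idx <- sample.int(length_aa, n_mut)
          for (i in idx) prot[i] <- sample(setdiff(AA20, prot[i]), 1L)
        }
        cds <- paste(CODON_OF[prot], collapse = "")
        if (!is.na(inter_genome) && g == inter_genome) {
          cut <- floor(length_aa / 2)
          prot5 <- paste(prot[1:cut], collapse = "")
          prot3 <- paste(prot[(cut + 1):length_aa], collapse = "")
          cds5 <- paste(CODON_OF[prot[1:cut]], collapse = "")
          cds3 <- paste(CODON_OF[prot[(cut + 1):length_aa]], collapse = "")
          # the artifact: original CDS reads stop + restart mid-gene
          genes[[length(genes) + 1L]] <- gene_record(
            sprintf("genome%02d", g), sprintf("fam%d_5prime", f), prot5,
            cds = paste0(cds5, "TAA"))
          genes[[length(genes) + 1L]] <- gene_record(
            sprintf("genome%02d", g), sprintf("fam%d_3prime", f), prot3,
            cds = paste0("ATG", cds3))
        } else {
          genes[[length(genes) + 1L]] <- gene_record(
            sprintf("genome%02d", g), sprintf("fam%d", f),
            paste(prot, collapse = ""), cds = cds)
        }
      }
      truth[[f]] <- data.frame(
        family = sprintf("fam%d", f),
        carriers = paste(sprintf("genome%02d", sort(carriers)),
                         collapse = ","),
        interrupted_genome = if (is.na(inter_genome)) NA_character_ else
          sprintf("genome%02d", inter_genome),
        stringsAsFactors = FALSE)
    }
  })
  list(genes = genes, truth = do.call(rbind, truth))
}

#' Simulate a pair of genuinely duplicated, divergent gene copies
#'
#' Control case for [detect_interrupted()]: one genome carries two
#' full-length copies of a family at the stated mutual identity (a true
#' duplication, not a fragment pair).
#'
#' @param n_genomes number of genomes; genome 1 carries the duplication.
#' @param identity target percent identity between copies and ancestor.
#' @param seed integer.
#' @param length_aa protein length.
#' @return list of `gene_record`s.
#' @export
simulate_duplicated_family <- function(n_genomes, identity = 80, seed = 1L,
                                       length_aa = 250L) {
  withr::with_seed(seed, {
    anc <- sample(AA20, length_aa, replace = TRUE)
    mk <- function() {
      prot <- anc
      n_mut <- stats::rbinom(1L, length_aa, 1 - sqrt(identity / 100))
      if (n_mut > 0L) {
        for (i in sample.int(length_aa, n_mut)) {
          prot[i] <- sample(setdiff(AA20, prot[i]), 1L)
        }
      }
      prot
    }
    genes <- list()
    for (g in seq_len(n_genomes)) {
      prot <- mk()
      genes[[length(genes) + 1L]] <- gene_record(
        sprintf("genome%02d", g), "dup_a", paste(prot, collapse = ""),
        cds = paste(CODON_OF[prot], collapse = ""))
    }
    prot2 <- mk()
    genes[[length(genes) + 1L]] <- gene_record(
      "genome01", "dup_b", paste(prot2, collapse = ""),
      cds = paste(CODON_OF[prot2], collapse = ""))
  })
  genes
}
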