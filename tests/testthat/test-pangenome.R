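test_that("percent identity is shorter-length normalized and symmetric", {
  a <- gene_record("g1", "x", "MKVLAT")
  expect_equal(pairwise_identity(a, a), 100)
  # exact prefix: normalized by the shorter length
  expect_equal(pairwise_identity("MKV", "MKVAAAA"), 100)
  b <- gene_record("g2", "y", "MKVLWT")
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))

  # 20-mers with 14 identities in the optimal (gapless here) alignment:
  # positions 15-20 substituted with dissimilar residues
  s1 <- "MKVLATGHERWQNDSYFILP"
  s2 <- "MKVLATGHERWQNDWEHRAG"
  expect_equal(pairwise_identity(s1, s2), 70)
})

test_that("clustering respects the threshold and classifies categories", {
  # 3 genomes, one perfect family -> single core cluster
  genes <- lapply(1:3, function(g) {
    gene_record(sprintf("genome%02d", g), "fam",
                strrep("MKVLATGHER", 10))
  })
  pg <- cluster_genes(genes, 90)
  expect_equal(length(pg$clusters), 1L)
  expect_equal(unname(pg$categories), "core")

  # presence thresholds: 9/10 soft-core, 10/10 core, 1/10 singleton
  fams <- data.frame(identity = c(100, 100, 100),
                     presence = c(1, 0.9, 0.1), interrupted = FALSE)
  gf <- simulate_gene_families(10, fams, seed = 4)
  pg2 <- cluster_genes(gf$genes, 70,
                       genomes = sprintf("genome%02d", 1:10))
  expect_setequal(unname(pg2$categories),
                  c("core", "soft_core", "singleton"))

  expect_equal(length(cluster_genes(list(), 70)$clusters), 0L)
  expect_error(cluster_genes(genes, 0), "threshold")
})

test_that("a 75%-identity family is one cluster at i=70, several at i=90", {
  gf <- simulate_gene_families(8, data.frame(identity = 75, presence = 1,
                                             interrupted = FALSE),
                               seed = 12)
  expect_equal(length(cluster_genes(gf$genes, 70)$clusters), 1L)
  expect_gt(length(cluster_genes(gf$genes, 90)$clusters), 1L)
})

test_that("clustering is invariant to gene input order", {
  gf <- simulate_gene_families(
    6, data.frame(identity = c(80, 60), presence = c(1, 0.8),
                  interrupted = FALSE), seed = 9)
  pg <- cluster_genes(gf$genes, 70)
  withr::with_seed(1, perm <- sample(length(gf$genes)))
  pg2 <- cluster_genes(gf$genes[perm], 70)
  norm <- function(p) {
    unname(lapply(p$clusters, sort))[order(vapply(
      lapply(p$clusters, sort), `[`, "", 1))]
  }
  expect_equal(norm(pg), norm(pg2))
})

test_that("sweep table is monotone in identity; split only refines", {
  fams <- data.frame(identity = c(95, 75, 55), presence = c(1, 1, 0.7),
                     interrupted = FALSE)
  gf <- simulate_gene_families(8, fams, seed = 31)
  sw <- pangenome_sweep(gf$genes, genomes = sprintf("genome%02d", 1:8))
  expect_equal(nrow(sw), 12L)
  for (split in c(FALSE, TRUE)) {
    sizes <- sw$pan_size[sw$split == split][order(sw$identity[sw$split ==
                                                                split])]
    expect_true(all(diff(sizes) >= 0))
  }
  # split=on never yields fewer clusters at the same threshold
  for (i in unique(sw$identity)) {
    expect_gte(sw$pan_size[sw$split & sw$identity == i],
               sw$pan_size[!sw$split & sw$identity == i])
  }
  # categories partition the pan
  expect_true(all(sw$core + sw$soft_core + sw$shell + sw$singleton ==
                    sw$pan_size))

  # single perfect family: pan size 1 everywhere
  mono <- simulate_gene_families(5, data.frame(identity = 100,
                                               presence = 1,
                                               interrupted = FALSE),
                                 seed = 2)
  sw1 <- pangenome_sweep(mono$genes)
  expect_true(all(sw1$pan_size == 1L))
})

test_that("interrupted-gene fragments are flagged; true duplicates are not", {
  fams <- data.frame(identity = c(90, 90), presence = c(1, 1),
                     interrupted = c(TRUE, FALSE))
  gf <- simulate_gene_families(6, fams, seed = 8)
  pg <- cluster_genes(gf$genes, 70)
  flags <- detect_interrupted(gf$genes, pg)
  expect_equal(nrow(flags), 1L)
  expect_equal(flags$genome_id, gf$truth$interrupted_genome[1])
  expect_true(flags$internal_stop)

  # genuinely duplicated divergent copies: no flag
  dup <- simulate_duplicated_family(5, identity = 80, seed = 3)
  pgd <- cluster_genes(dup, 70)
  flagd <- detect_interrupted(dup, pgd)
  expect_equal(nrow(flagd), 0L)

  # clusters with one member per genome: nothing to test
  clean <- simulate_gene_families(4, data.frame(identity = 90,
                                                presence = 1,
                                                interrupted = FALSE),
                                  seed = 5)
  expect_equal(nrow(detect_interrupted(clean$genes,
                                       cluster_genes(clean$genes, 70))),
               0L)

  # without CDS the check is skipped with a notice
  nocds <- lapply(clean$genes, function(g) { g$cds <- NULL; g })
  expect_message(
    out <- detect_interrupted(nocds, cluster_genes(nocds, 70)),
    "skipped")
  expect_null(out)
})

test_that("fragments co-cluster with the family when paralogs are unsplit", {
  gf <- simulate_gene_families(
    6, data.frame(identity = 95, presence = 1, interrupted = TRUE),
    seed = 14)
  pg_off <- cluster_genes(gf$genes, 70, split_paralogs = FALSE)
  # both fragments sit in the single family cluster
  expect_equal(length(pg_off$clusters), 1L)
  expect_equal(length(pg_off$clusters[[1]]), 7L)   # 5 full + 2 fragments
})
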