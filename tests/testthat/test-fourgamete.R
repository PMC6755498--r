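test_that("four-gamete incompatibility detects exactly the 4-type case", {
  expect_true(incompatible(c(0, 0, 1, 1), c(0, 1, 0, 1)))
  # three gamete types among 6 haplotypes
  expect_false(incompatible(c(0, 0, 0, 1, 1, 1), c(0, 1, 1, 1, 1, 1)))
  expect_error(incompatible(c(0, 0, 0, 0), c(0, 1, 0, 1)), "biallelic")
  expect_error(incompatible(c(0, 1), c(0, 1, 0)), "different")
})

test_that("rmin is zero for clonal data and one for a single conflict", {
  clonal <- haplotype_alignment(
    c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT", d = "ACGTACGT"),
    "nt")
  expect_equal(rmin(clonal)$rmin, 0L)

  # two sites with all four gametes
  one <- haplotype_alignment(
    c(a = "AAAA", b = "AATA", c = "TAAA", d = "TATA"), "nt")
  r <- rmin(one)
  expect_equal(r$rmin, 1L)
  expect_equal(nrow(r$breakpoints), 1L)
  # breakpoint interval lies between the two conflicting columns (0 and 2)
  expect_gte(r$breakpoints$start, 1L)
  expect_lte(r$breakpoints$end, 2L)

  # two haplotypes can never show four gametes
  two <- haplotype_alignment(c(a = "ACAC", b = "CACA"), "nt")
  expect_equal(rmin(two)$rmin, 0L)
})

test_that("greedy interval selection equals exhaustive minimum cover", {
  withr::with_seed(42, {
    for (case in 1:60) {
      n_h <- sample(4:8, 1)
      n_s <- sample(4:12, 1)
      mat <- matrix(sample(0:1, n_h * n_s, replace = TRUE), n_h, n_s)
      # keep biallelic columns only, mirroring the production filter
      keep <- apply(mat, 2, function(x) length(unique(x)) == 2)
      mat <- mat[, keep, drop = FALSE]
      if (ncol(mat) < 2) next
      positions <- sort(sample(0:(5 * n_s), ncol(mat)))
      seqs <- apply(mat, 1, function(row) {
        full <- rep("A", max(positions) + 1)
        full[positions + 1] <- c("A", "T")[row + 1]
        paste(full, collapse = "")
      })
      names(seqs) <- sprintf("h%d", seq_len(n_h))
      aln <- haplotype_alignment(seqs, "nt")
      got <- rmin(aln)
      iv <- incompatible_intervals(mat, positions)
      want <- exhaustive_min_breakpoints(iv, positions)
      expect_equal(got$rmin, want)
    }
  })
})

test_that("rmin is invariant to reordering and allele relabeling", {
  sim <- simulate_recombining_gene(8, 200, 2, seed = 77)
  base <- rmin(sim$alignment)$rmin
  # reorder haplotypes
  perm <- rev(sim$alignment$sequences)
  expect_equal(rmin(haplotype_alignment(perm, "nt"))$rmin, base)
  # swap alleles at the first segregating site (complement the column)
  m <- do.call(rbind, strsplit(sim$alignment$sequences, ""))
  seg <- which(apply(m, 2, function(x) length(unique(x)) == 2))[1]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m[, seg] <- comp[m[, seg]]
  seqs2 <- setNames(apply(m, 1, paste, collapse = ""),
                    names(sim$alignment$sequences))
  expect_equal(rmin(haplotype_alignment(seqs2, "nt"))$rmin, base)
})

test_that("rmin respects the planted crossover bound and S - 1", {
  for (seed in 1:25) {
    k <- seed %% 4
    sim <- simulate_recombining_gene(10, 150, k, seed = seed)
    st <- gene_stats("g", sim$alignment)
    expect_lte(st$rmin, k)
    expect_lte(st$rmin, max(st$S - 1, 0))
  }
})

test_that("a crossover separating incompatible-making sites yields rmin 1", {
  # constructed: parents differ at two sites; one crossover between them
  seqs <- c(h1 = "AAAAAA", h2 = "TAAAAT", h3 = "TAAAAA", h4 = "AAAAAT")
  # sites 0 and 5: gametes AA, TT, TA, AT -> all four
  r <- rmin(haplotype_alignment(seqs, "nt"))
  expect_equal(r$rmin, 1L)
})

test_that("gap columns are removed before pairing", {
  # the gapped column would otherwise form an incompatible pair
  seqs <- c(h1 = "A-AA", h2 = "T-AT", h3 = "TAAA", h4 = "A-AT")
  r <- rmin(haplotype_alignment(seqs, "nt"))
  # column 2 (gapped) is dropped; remaining sites 0 and 3 have gametes
  # A/A, T/T, T/A, A/T -> four gametes -> rmin 1
  expect_equal(r$rmin, 1L)
  expect_equal(r$n_incompatible_pairs, 1L)
})

test_that("regression recovers a noiseless plane exactly", {
  withr::with_seed(6, {
    stats <- data.frame(gene_id = sprintf("g%d", 1:12),
                        pi = runif(12, 0, 0.2),
                        n = sample(10:30, 12, replace = TRUE))
  })
  stats$rmin_per_nt <- 0.01 + 2 * stats$pi + 0.001 * stats$n
  stats$rmin <- NA; stats$L <- 500; stats$S <- NA
  fit <- regress(stats)
  expect_equal(fit$beta0, 0.01, tolerance = 1e-10)
  expect_equal(fit$beta1, 2, tolerance = 1e-10)
  expect_equal(fit$beta2, 0.001, tolerance = 1e-10)
  expect_true(all(abs(fit$residuals) < 1e-12))
  # line holds x2 at the mean n
  expect_equal(fit$line_at_mean_n(0.1),
               0.01 + 0.2 + 0.001 * mean(stats$n), tolerance = 1e-10)

  # affine equivariance: shifting y moves only the intercept
  shifted <- stats; shifted$rmin_per_nt <- stats$rmin_per_nt + 0.5
  fit2 <- regress(shifted)
  expect_equal(fit2$beta0, fit$beta0 + 0.5, tolerance = 1e-10)
  expect_equal(fit2$beta1, fit$beta1, tolerance = 1e-10)
  expect_equal(fit2$beta2, fit$beta2, tolerance = 1e-10)
})

test_that("coefficients equal the normal-equations solution", {
  withr::with_seed(9, {
    stats <- data.frame(gene_id = sprintf("g%d", 1:6),
                        pi = c(0.01, 0.05, 0.08, 0.02, 0.12, 0.07),
                        n = c(20, 24, 18, 27, 22, 25))
    stats$rmin_per_nt <- 0.02 + 1.5 * stats$pi + 0.0005 * stats$n +
      rnorm(6, 0, 0.003)
  })
  fit <- regress(stats)
  beta <- normal_equations(stats$rmin_per_nt,
                           cbind(1, stats$pi, stats$n))
  expect_equal(c(fit$beta0, fit$beta1, fit$beta2), unname(beta),
               tolerance = 1e-10)
  expect_lt(abs(sum(fit$residuals)), 1e-10)
})

test_that("constant n drops x2 with a warning; outliers are flagged", {
  stats <- data.frame(gene_id = sprintf("g%d", 1:6),
                      pi = c(0.01, 0.05, 0.08, 0.02, 0.12, 0.07),
                      n = 20)
  stats$rmin_per_nt <- 0.02 + 1.5 * stats$pi
  expect_warning(fit <- regress(stats), "constant")
  expect_true(is.na(fit$beta2))
  expect_equal(fit$beta1, 1.5, tolerance = 1e-10)

  # planted outlier: only that gene deviates
  withr::with_seed(10, {
    stats2 <- data.frame(gene_id = sprintf("g%d", 1:12),
                         pi = runif(12, 0.02, 0.2),
                         n = sample(15:30, 12, replace = TRUE))
  })
  stats2$rmin_per_nt <- 0.01 + 1.2 * stats2$pi + 0.0008 * stats2$n
  stats2$rmin_per_nt[5] <- stats2$rmin_per_nt[5] * 5
  stats2$rmin <- NA
  fit2 <- regress(stats2)
  rep2 <- intensity_report(stats2, fit2)
  expect_equal(nrow(rep2), 12L)
  expect_equal(rep2$gene_id[rep2$deviating], "g5")

  # all on the line: nothing deviates
  stats2$rmin_per_nt[5] <- 0.01 + 1.2 * stats2$pi[5] + 0.0008 * stats2$n[5]
  rep3 <- intensity_report(stats2, regress(stats2))
  expect_false(any(rep3$deviating))
})
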