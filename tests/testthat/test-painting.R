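# small hand-built SNP sets are assembled directly as snp_haplotypes-shaped
# objects through extract_core_snps on constructed alignments
snps_from_matrix <- function(mat, positions) {
  structure(list(matrix = mat, positions = positions,
                 distances = diff(positions), labels = NULL),
            class = "snp_haplotypes")
}

test_that("copy posterior matches exhaustive path enumeration", {
  # 3 SNPs, recipient + 2 donors; several parameter settings and allele
  # configurations
  cases <- list(
    list(rec = c(0L, 1L, 0L), donors = rbind(c(0L, 1L, 1L), c(1L, 1L, 0L)),
         pos = c(0L, 50L, 300L), scale = 0.01, mis = 0.05),
    list(rec = c(1L, 1L, 1L), donors = rbind(c(1L, 0L, 1L), c(0L, 1L, 1L)),
         pos = c(10L, 20L, 30L), scale = 0.05, mis = 0.2),
    list(rec = c(0L, 0L, 1L), donors = rbind(c(0L, 0L, 0L), c(1L, 0L, 1L)),
         pos = c(0L, 1000L, 1500L), scale = 0.001, mis = 0.01)
  )
  for (cs in cases) {
    mat <- rbind(cs$rec, cs$donors)
    rownames(mat) <- c("rec", "d1", "d2")
    snps <- snps_from_matrix(mat, cs$pos)
    got <- paint_recipient(snps, "rec", painting_params(cs$scale, cs$mis))
    want <- enum_painting(cs$rec, cs$donors, cs$pos, cs$scale, cs$mis)
    expect_equal(unname(got$copy_posterior), want$post, tolerance = 1e-10)
    expect_equal(unname(got$expected_chunks), want$chunks,
                 tolerance = 1e-10)
  }
})

test_that("posterior rows sum to one and chunks total at least one", {
  sim <- simulate_populations(sim_config(n_pops = 2, pop_sizes = c(5, 5),
                                         genome_len = 8000, seed = 3))
  snps <- extract_core_snps(sim$alignment)
  params <- estimate_params(snps)
  for (r in c(1L, 4L, 10L)) {
    p <- paint_recipient(snps, r, params)
    expect_true(all(abs(rowSums(p$copy_posterior) - 1) < 1e-9))
    expect_gte(sum(p$expected_chunks), 1 - 1e-9)
    expect_true(all(p$expected_chunks >= 0))
    expect_true(is.finite(p$log_lik))
  }
})

test_that("dominant donor takes the posterior; identical donors split it", {
  # recipient identical to donor A, donor B maximally mismatched
  L <- 20L
  rec <- rep(c(0L, 1L), 10L)
  mat <- rbind(rec = rec, A = rec, B = 1L - rec)
  snps <- snps_from_matrix(mat, seq(0L, by = 100L, length.out = L))
  p <- paint_recipient(snps, "rec", painting_params(1e-5, 0.01))
  expect_true(all(p$copy_posterior[, "A"] > 0.99))
  expect_lt(p$expected_chunks["B"], 0.01)

  # two donors both identical to the recipient: exchangeable
  mat2 <- rbind(rec = rec, A = rec, B = rec)
  snps2 <- snps_from_matrix(mat2, seq(0L, by = 100L, length.out = L))
  p2 <- paint_recipient(snps2, "rec", painting_params(1e-3, 0.05))
  expect_equal(p2$expected_chunks[["A"]], p2$expected_chunks[["B"]],
               tolerance = 1e-12)
})

test_that("painting commutes with donor relabeling", {
  sim <- simulate_populations(sim_config(n_pops = 2, pop_sizes = c(4, 4),
                                         genome_len = 4000, seed = 8))
  snps <- extract_core_snps(sim$alignment)
  params <- estimate_params(snps)
  p <- paint_recipient(snps, 2L, params)
  # permute sample order (recipient stays identifiable by name)
  perm <- c(3L, 1L, 2L, 8L, 5L, 4L, 7L, 6L)
  snps_p <- snps_from_matrix(snps$matrix[perm, ], snps$positions)
  p2 <- paint_recipient(snps_p, rownames(snps$matrix)[2L], params)
  donors <- names(p$expected_chunks)
  expect_equal(p2$expected_chunks[donors], p$expected_chunks[donors],
               tolerance = 1e-12)
})

test_that("default parameters follow the stated conventions", {
  sim <- simulate_populations(sim_config(n_pops = 2, pop_sizes = c(3, 3),
                                         genome_len = 3000, seed = 5))
  snps <- extract_core_snps(sim$alignment)
  params <- estimate_params(snps)
  # k = 5 donors: theta_w = 1/(1 + 1/2 + 1/3 + 1/4) = 12/25
  theta <- 12 / 25
  expect_equal(params$miscopy, theta / (theta + 10), tolerance = 1e-12)
  expect_equal(params$switch_scale, 10 / sum(snps$distances),
               tolerance = 1e-12)
  # overrides are echoed
  p2 <- estimate_params(snps, switch_scale = 0.001, miscopy = 0.2)
  expect_equal(p2$switch_scale, 0.001)
  expect_equal(p2$miscopy, 0.2)
  expect_error(painting_params(0, 0.1), "switch_scale")
  expect_error(painting_params(1, 0.6), "miscopy")
})

test_that("co-ancestry matrix has zero diagonal and block structure", {
  sim <- simulate_populations(sim_config(
    n_pops = 2, pop_sizes = c(5, 5), genome_len = 10000,
    divergence = 0.03, seed = 21))
  snps <- extract_core_snps(sim$alignment)
  cm <- coancestry(snps)
  expect_true(all(diag(cm$X) == 0))
  expect_true(all(cm$X >= 0))
  expect_true(all(rowSums(cm$X) > 0))
  pop <- sim$labels[rownames(cm$X)]
  same <- outer(pop, pop, "==") & !diag(TRUE, nrow(cm$X))
  within <- mean(cm$X[same])
  between <- mean(cm$X[!same & !diag(TRUE, nrow(cm$X))])
  expect_gt(within, between)
})

test_that("chunk share from a donor population rises with migration", {
  frac_from_b <- function(m, seed) {
    M <- rbind(c(1 - m, m), c(0, 1))
    sim <- simulate_populations(sim_config(
      n_pops = 2, pop_sizes = c(4, 8), genome_len = 15000,
      migration = M, segment_mean = 1500, seed = seed))
    snps <- extract_core_snps(sim$alignment)
    cm <- coancestry(snps, estimate_params(snps, switch_scale = 1 / 1500))
    ft <- import_fractions(cm, sim$labels)
    median(ft$fraction[ft$recipient_pop == "pop1" &
                         ft$donor_pop == "pop2"])
  }
  vals <- vapply(c(0, 0.1, 0.3), frac_from_b, 0, seed = 99)
  expect_true(all(diff(vals) > 0))
})
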