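# Independent oracles used across the suite. Each is a deliberately naive,
# brute-force implementation kept separate from the package's algorithms.

# --- copying HMM by exhaustive path enumeration (small L, k only) --------
# returns per-site posterior and expected chunk counts per donor under the
# same model: uniform initial donor, switch prob s_l = 1 - exp(-scale*d_l)
# then uniform new donor, emission (1-miscopy)/miscopy on match/mismatch.
enum_painting <- function(rec, donors, positions, switch_scale, miscopy) {
  L <- length(rec)
  k <- nrow(donors)
  d <- diff(positions)
  s <- 1 - exp(-switch_scale * d)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), L)))
  probs <- numeric(nrow(paths))
  for (p in seq_len(nrow(paths))) {
    z <- paths[p, ]
    pr <- 1 / k
    for (l in seq_len(L)) {
      e <- if (donors[z[l], l] == rec[l]) 1 - miscopy else miscopy
      pr <- pr * e
      if (l < L) {
        trans <- (1 - s[l]) * (z[l + 1] == z[l]) + s[l] / k
        pr <- pr * trans
      }
    }
    probs[p] <- pr
  }
  probs <- probs / sum(probs)
  post <- matrix(0, L, k)
  chunks <- numeric(k)
  for (p in seq_len(nrow(paths))) {
    z <- paths[p, ]
    for (l in seq_len(L)) post[l, z[l]] <- post[l, z[l]] + probs[p]
    chunks[z[1]] <- chunks[z[1]] + probs[p]
    if (L > 1) {
      for (l in seq_len(L - 1)) {
        if (z[l + 1] != z[l]) {
          chunks[z[l + 1]] <- chunks[z[l + 1]] + probs[p]
        }
      }
    }
  }
  list(post = post, chunks = chunks)
}

# --- minimum breakpoint count by exhaustive gap-subset search ------------
# intervals: matrix of open intervals (a, b) in site-position coordinates;
# positions: sorted site positions. A breakpoint lives in a gap between
# adjacent sites; the minimum number of gaps hitting every interval is
# found by brute force over gap subsets of increasing size.
exhaustive_min_breakpoints <- function(intervals, positions) {
  if (nrow(intervals) == 0) return(0L)
  S <- length(positions)
  gaps <- cbind(positions[-S], positions[-1])   # gap i = (p_i, p_{i+1})
  hits <- function(gap, iv) iv[1] <= gap[1] && gap[2] <= iv[2]
  covers <- matrix(FALSE, nrow(gaps), nrow(intervals))
  for (g in seq_len(nrow(gaps))) {
    for (i in seq_len(nrow(intervals))) {
      covers[g, i] <- hits(gaps[g, ], intervals[i, ])
    }
  }
  for (size in seq_len(nrow(gaps))) {
    subsets <- utils::combn(nrow(gaps), size)
    for (cc in seq_len(ncol(subsets))) {
      chosen <- subsets[, cc]
      if (all(colSums(covers[chosen, , drop = FALSE]) > 0)) {
        return(size)
      }
    }
  }
  stop("no covering subset found")
}

# incompatible site pairs of a 0/1 haplotype matrix, as (pos_a, pos_b) rows
incompatible_intervals <- function(mat, positions) {
  S <- ncol(mat)
  out <- list()
  if (S >= 2) {
    for (i in seq_len(S - 1)) {
      for (j in seq.int(i + 1, S)) {
        gam <- unique(paste(mat[, i], mat[, j]))
        if (length(gam) == 4) {
          out[[length(out) + 1]] <- c(positions[i], positions[j])
        }
      }
    }
  }
  if (length(out) == 0) {
    matrix(numeric(), 0, 2)
  } else {
    do.call(rbind, out)
  }
}

# --- exact Wilcoxon two-sided p by full enumeration ----------------------
enum_ranksum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  ranks <- rank(c(a, b))
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  subsets <- utils::combn(N, n1)
  us <- apply(subsets, 2, function(s) sum(seq_len(N)[s]) - n1 * (n1 + 1) / 2)
  min(1, mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12))
}

# --- partition likelihood from first principles for integer counts -------
# explicit factorial/product evaluation of the per-row marginal: chunks
# drawn one donor at a time with prob q_b/n_b (own cluster loses self),
# q ~ Dirichlet(beta); for integer counts the DM mass has a factorial form.
factorial_log_ml <- function(X, assign_vec, beta) {
  samples <- rownames(X)
  labs <- unique(assign_vec[samples])
  K <- length(labs)
  total <- 0
  for (r in samples) {
    x <- sapply(labs, function(b) {
      donors <- setdiff(samples[assign_vec[samples] == b], r)
      sum(X[r, donors])
    })
    nr <- sum(x)
    dm <- lgamma(K * beta) - lgamma(nr + K * beta) +
      sum(lgamma(x + beta) - lgamma(beta))
    spread <- 0
    for (bi in seq_along(labs)) {
      nb <- length(setdiff(samples[assign_vec[samples] == labs[bi]], r))
      if (x[bi] > 0) spread <- spread + x[bi] * log(nb)
    }
    total <- total + unname(dm - spread)
  }
  total
}

# --- ordinary least squares via the normal equations ---------------------
normal_equations <- function(y, X) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# --- shared synthetic block co-ancestry matrix ---------------------------
block_coancestry <- function(n_per_block = 8, n_blocks = 3, contrast = 20,
                             seed = 1) {
  withr::with_seed(seed, {
    n <- n_per_block * n_blocks
    pops <- rep(seq_len(n_blocks), each = n_per_block)
    X <- matrix(stats::rgamma(n * n, 2, 1), n, n)
    X[outer(pops, pops, "==")] <- X[outer(pops, pops, "==")] + contrast
    diag(X) <- 0
    rownames(X) <- colnames(X) <- sprintf("s%02d", seq_len(n))
  })
  list(X = X, pops = pops)
}

# does a partition match planted integer block labels exactly (up to names)?
matches_blocks <- function(part, pops) {
  tab <- table(part$assignment, pops)
  part$K == length(unique(pops)) &&
    all(colSums(tab > 0) == 1) && all(rowSums(tab > 0) == 1)
}
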