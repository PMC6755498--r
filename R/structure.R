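#' Partition of individuals into clusters
#'
#' @param assignment named character (or factor) vector: sample id -> cluster
#'   label.
#' @param log_ml optional log marginal likelihood of the partition.
#' @param tree optional Newick string recording the greedy merge order.
#' @return object of class `partition`: list with `assignment`, `K`,
#'   `log_ml`, `tree`.
#' @export
partition <- function(assignment, log_ml = NA_real_, tree = NULL) {
  assignment <- stats::setNames(as.character(assignment), names(assignment))
  if (is.null(names(assignment)) || anyDuplicated(names(assignment))) {
    stop("assignment must be named by unique sample ids", call. = FALSE)
  }
  structure(list(assignment = assignment,
                 K = length(unique(assignment)),
                 log_ml = log_ml, tree = tree),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d samples in %d clusters (log ML %.3f)\n",
              length(x$assignment), x$K, x$log_ml))
  invisible(x)
}

#' MCMC configuration for partition sampling
#'
#' @param burn_in,iterations positive integers; defaults follow the
#'   convention of running equally long burn-in and sampling chains of 1e5.
#' @param seed integer RNG seed.
#' @param dirichlet_beta symmetric Dirichlet concentration (> 0).
#' @param thin record every `thin`-th post-burn-in partition.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(burn_in = 100000L, iterations = 100000L,
                        seed = 1L, dirichlet_beta = 1, thin = 100L) {
  stopifnot(burn_in >= 1, iterations >= 1, dirichlet_beta > 0, thin >= 1)
  structure(list(burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed),
                 dirichlet_beta = dirichlet_beta,
                 thin = as.integer(thin)),
            class = "mcmc_config")
}

# integer cluster codes for fast likelihood evaluation
as_codes <- function(assignment, samples) {
  z <- assignment[samples]
  match(z, unique(z))
}

# row-wise Dirichlet-multinomial log marginal likelihood on donor-cluster
# aggregated counts; z is an integer vector of cluster codes 1..K. Each
# recipient row is a draw over donor individuals with probability q_b/n_b
# for a donor in cluster b (q ~ symmetric Dirichlet over clusters, chunks
# spread uniformly within a cluster); marginalizing q gives the DM term and
# the within-cluster spread gives the -x_rb log(n_b) term, which makes
# likelihoods comparable across partitions of different K. The recipient is
# excluded from its own cluster's donor count (leave-one-out panel).
log_ml_codes <- function(X, z, beta) {
  K <- max(z)
  n <- nrow(X)
  Z <- matrix(0, ncol(X), K)
  Z[cbind(seq_along(z), z)] <- 1
  agg <- X %*% Z                               # agg[r, b]
  nr <- rowSums(agg)
  sizes <- tabulate(z, K)
  # effective donor count per (recipient, cluster): own cluster loses self
  eff <- matrix(sizes, n, K, byrow = TRUE)
  eff[cbind(seq_len(n), z[seq_len(n)])] <-
    eff[cbind(seq_len(n), z[seq_len(n)])] - 1L
  spread <- sum(agg * log(pmax(eff, 1L)))      # x=0 cells contribute 0
  sum(lgamma(K * beta) - lgamma(nr + K * beta)) +
    sum(lgamma(agg + beta)) - n * K * lgamma(beta) - spread
}

#' Log marginal likelihood of a partition given a co-ancestry matrix
#'
#' Each recipient row of the chunk-count matrix is modelled as draws over
#' donor individuals, with a donor in cluster b drawn with probability
#' `q_b / n_b` (cluster proportions q under a symmetric Dirichlet prior
#' with concentration `beta`; chunks spread uniformly within a cluster,
#' the recipient excluded from its own cluster's donor count).
#' Marginalizing q gives a Dirichlet-multinomial over the cluster-aggregated
#' counts x_rb plus a `-sum x_rb log n_b` uniform-spread term; the latter is
#' what makes partitions of different K comparable. Real-valued expected
#' counts are handled through the continuous Gamma extension of the
#' factorials. The total is the sum of per-recipient contributions and is
#' invariant under cluster relabelling.
#'
#' @param cm a `coancestry_matrix` (or bare non-negative matrix with
#'   dimnames).
#' @param part a `partition` covering all samples of `cm`.
#' @param beta Dirichlet concentration (> 0), default 1.
#' @return scalar log marginal likelihood.
#' @export
partition_log_ml <- function(cm, part, beta = 1) {
  X <- if (inherits(cm, "coancestry_matrix")) cm$X else cm
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  if (any(X < 0)) stop("negative counts in co-ancestry matrix", call. = FALSE)
  samples <- rownames(X)
  if (!all(samples %in% names(part$assignment))) {
    stop("partition does not cover all samples", call. = FALSE)
  }
  log_ml_codes(X, as_codes(part$assignment, samples), beta)
}

# normalize codes to 1..K in order of first appearance (canonical form)
canon <- function(z) match(z, unique(z))

#' Metropolis-Hastings MCMC over partitions
#'
#' Samples partitions of the co-ancestry matrix under the
#' Dirichlet-multinomial marginal likelihood with a flat prior over
#' partitions. Two move types: (i) reassign a uniformly chosen individual to
#' a uniformly chosen other cluster or a new singleton; (ii) merge a uniform
#' random cluster pair, or split a uniform random cluster by a uniform random
#' non-trivial bipartition. Hastings corrections account for the asymmetric
#' proposals. The burn-in is discarded; the highest-likelihood partition
#' visited anywhere in the run is retained as the MAP estimate. Fully
#' reproducible from `cfg$seed`.
#'
#' @param cm a `coancestry_matrix` (or bare matrix with dimnames).
#' @param cfg an `mcmc_config`.
#' @param init optional initial `partition`; defaults to all-singletons.
#' @return list with `map` (a `partition` with `log_ml`), `samples` (list of
#'   thinned post-burn-in assignments), `trace` (data.frame: iteration, K,
#'   log_ml), `acceptance_rate`.
#' @export
run_mcmc <- function(cm, cfg = mcmc_config(), init = NULL) {
  X <- if (inherits(cm, "coancestry_matrix")) cm$X else cm
  samples <- rownames(X)
  n <- length(samples)
  beta <- cfg$dirichlet_beta
  z <- if (is.null(init)) seq_len(n) else as_codes(init$assignment, samples)
  z <- canon(z)

  withr::with_seed(cfg$seed, {
    cur_ll <- log_ml_codes(X, z, beta)
    if (!is.finite(cur_ll)) stop("non-finite initial likelihood",
                                 call. = FALSE)
    best_z <- z; best_ll <- cur_ll
    total <- cfg$burn_in + cfg$iterations
    kept <- list()
    trace_it <- integer(); trace_k <- integer(); trace_ll <- numeric()
    accepted <- 0L

    for (it in seq_len(total)) {
      K <- max(z)
      move <- if (stats::runif(1) < 0.5) "reassign" else "mergesplit"
      prop <- NULL; log_q_ratio <- 0

      if (move == "reassign") {
        i <- sample.int(n, 1L)
        cur <- z[i]
        size_cur <- sum(z == cur)
        # targets: every other existing cluster, plus a new singleton unless
        # i already is one
        targets <- setdiff(seq_len(K), cur)
        if (size_cur > 1L) targets <- c(targets, K + 1L)
        if (length(targets) == 0L) next
        tgt <- targets[sample.int(length(targets), 1L)]
        zp <- z; zp[i] <- tgt
        zp <- canon(zp)
        # reverse move counts from the proposed state
        Kp <- max(zp)
        size_new <- sum(zp == zp[i])
        n_fwd <- length(targets)
        n_rev <- (Kp - 1L) + as.integer(size_new > 1L)
        log_q_ratio <- log(n_fwd) - log(n_rev)
        prop <- zp
      } else {
        if (stats::runif(1) < 0.5) {
          # merge two uniformly chosen clusters
          if (K < 2L) next
          pair <- sample.int(K, 2L)
          zp <- z
          zp[zp == pair[2L]] <- pair[1L]
          zp <- canon(zp)
          m <- sum(z == pair[1L] | z == pair[2L])
          # reverse: split the merged cluster back into this bipartition
          Kp <- max(zp)
          splittable <- sum(tabulate(zp, Kp) >= 2L)
          log_q_fwd <- -log(choose(K, 2))
          log_q_rev <- -log(splittable) + log(2) - log(2^m - 2)
          log_q_ratio <- log_q_fwd - log_q_rev
          prop <- zp
        } else {
          # split a uniformly chosen cluster with >= 2 members
          sizes <- tabulate(z, K)
          cand <- which(sizes >= 2L)
          if (length(cand) == 0L) next
          cl <- cand[sample.int(length(cand), 1L)]
          members <- which(z == cl)
          m <- length(members)
          repeat {
            side <- stats::runif(m) < 0.5
            if (any(side) && !all(side)) break
          }
          zp <- z
          zp[members[side]] <- K + 1L
          zp <- canon(zp)
          log_q_fwd <- -log(length(cand)) + log(2) - log(2^m - 2)
          log_q_rev <- -log(choose(max(zp), 2))
          log_q_ratio <- log_q_fwd - log_q_rev
          prop <- zp
        }
      }

      if (is.null(prop)) next
      prop_ll <- log_ml_codes(X, prop, beta)
      if (!is.finite(prop_ll)) {
        stop(sprintf("non-finite likelihood at iteration %d (K=%d)",
                     it, max(prop)), call. = FALSE)
      }
      if (log(stats::runif(1)) < (prop_ll - cur_ll) - log_q_ratio) {
        z <- prop; cur_ll <- prop_ll; accepted <- accepted + 1L
        if (cur_ll > best_ll) { best_ll <- cur_ll; best_z <- z }
      }
      if (it > cfg$burn_in) {
        rec <- it - cfg$burn_in
        if (rec %% cfg$thin == 0L) {
          kept[[length(kept) + 1L]] <-
            stats::setNames(as.character(z), samples)
          trace_it <- c(trace_it, it)
          trace_k <- c(trace_k, max(z))
          trace_ll <- c(trace_ll, cur_ll)
        }
      }
    }
  })

  map <- partition(stats::setNames(as.character(best_z), samples),
                   log_ml = best_ll)
  list(map = map, samples = kept,
       trace = data.frame(iteration = trace_it, K = trace_k,
                          log_ml = trace_ll),
       acceptance_rate = accepted / (cfg$burn_in + cfg$iterations))
}

#' Greedy merge tree over MAP clusters
#'
#' Starting from the MAP partition, repeatedly merges the cluster pair whose
#' merge loses the least log marginal likelihood until a single cluster
#' remains; ties break on the lexicographically smallest label pair. The
#' merge order is recorded as a rooted Newick tree whose leaves are the MAP
#' clusters (branch lengths = cumulative log-likelihood loss at the merge).
#'
#' @param cm a `coancestry_matrix` (or bare matrix with dimnames).
#' @param map_partition a `partition`.
#' @param beta Dirichlet concentration, default 1.
#' @return the input `partition` with its `tree` field set to a Newick
#'   string, plus attribute `merges` (data.frame of the merge sequence).
#' @export
merge_tree <- function(cm, map_partition, beta = 1) {
  X <- if (inherits(cm, "coancestry_matrix")) cm$X else cm
  samples <- rownames(X)
  assignment <- map_partition$assignment[samples]
  labels <- sort(unique(assignment))
  groups <- lapply(labels, function(l) samples[assignment == l])
  names(groups) <- labels
  newick <- stats::setNames(as.name_safe(labels), labels)
  merges <- data.frame(a = character(), b = character(), loss = numeric(),
                       stringsAsFactors = FALSE)

  score <- function(groups) {
    z <- integer(length(samples))
    for (b in seq_along(groups)) z[match(groups[[b]], samples)] <- b
    log_ml_codes(X, z, beta)
  }

  cur <- score(groups)
  height <- 0
  while (length(groups) > 1L) {
    labs <- names(groups)
    best <- NULL
    for (i in seq_len(length(groups) - 1L)) {
      for (j in seq.int(i + 1L, length(groups))) {
        g2 <- groups
        g2[[i]] <- c(g2[[i]], g2[[j]])
        g2[[j]] <- NULL
        s <- score(g2)
        cand <- list(i = i, j = j, s = s)
        if (is.null(best) || s > best$s + 1e-12) best <- cand
        # strict ">" with tolerance keeps the lexicographically first pair
        # on ties because (i, j) enumerate in sorted label order
      }
    }
    loss <- cur - best$s
    height <- height + max(loss, 0)
    merges <- rbind(merges, data.frame(
      a = labs[best$i], b = labs[best$j], loss = loss,
      stringsAsFactors = FALSE))
    newick_new <- sprintf("(%s,%s):%.6g",
                          newick[[labs[best$i]]], newick[[labs[best$j]]],
                          max(loss, 0))
    groups[[best$i]] <- c(groups[[best$i]], groups[[best$j]])
    groups[[best$j]] <- NULL
    newick <- newick[setdiff(names(newick), c(labs[best$i], labs[best$j]))]
    newick[[labs[best$i]]] <- newick_new
    cur <- best$s
  }
  out <- partition(assignment, log_ml = map_partition$log_ml,
                   tree = paste0(sub(":[0-9.eE+-]+$", "", newick[[1L]]), ";"))
  attr(out, "merges") <- merges
  out
}

# cluster labels as safe newick leaf names
as.name_safe <- function(x) gsub("[(),:;\\s]", "_", x, perl = TRUE)

#' Write a partition as a two-column TSV
#' @param part a `partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path) {
  utils::write.table(
    data.frame(sample = names(part$assignment),
               cluster = unname(part$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
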