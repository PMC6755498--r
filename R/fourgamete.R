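#' Four-gamete incompatibility of two biallelic sites
#'
#' Under infinite sites, two biallelic sites showing all four allele
#' combinations (00, 01, 10, 11) among the haplotypes cannot descend from a
#' single tree without at least one recombination event between them.
#'
#' @param site_a,site_b vectors of allele states over the same haplotypes
#'   (any two-level coding; gap-containing columns must be removed
#'   upstream).
#' @return `TRUE` iff all four gametic types occur.
#' @export
incompatible <- function(site_a, site_b) {
  if (length(site_a) != length(site_b)) {
    stop("sites cover different haplotype sets", call. = FALSE)
  }
  if (length(unique(site_a)) != 2L || length(unique(site_b)) != 2L) {
    stop("four-gamete test requires biallelic sites", call. = FALSE)
  }
  nrow(unique(cbind(site_a, site_b))) == 4L
}

#' Hudson-Kaplan minimum number of recombination events
#'
#' Removes gap-containing columns, takes the biallelic segregating sites,
#' tests every site pair for four-gamete incompatibility, and reduces the
#' incompatible pairs - open intervals between the two site positions - to a
#' maximal set of pairwise non-overlapping intervals by scanning in order of
#' right endpoint and greedily accepting each interval starting at or after
#' the last accepted right endpoint. The count of accepted intervals is the
#' minimum number of recombination events consistent with the alignment;
#' this greedy rule is the optimal interval-scheduling solution, so the
#' bound is exact for the given incompatibility set.
#'
#' @param aln a nucleotide `haplotype_alignment` (N >= 4 recommended; with
#'   fewer than 4 haplotypes no pair can show four gametes).
#' @return list with `rmin` (integer), `breakpoints` (data.frame `start`,
#'   `end`: half-open 0-based intervals in original alignment coordinates),
#'   and `n_incompatible_pairs`.
#' @export
rmin <- function(aln) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  m <- aln_matrix(aln)
  keep <- !apply(m, 2L, function(col) any(col %in% c("-", "N")))
  m <- m[, keep, drop = FALSE]
  orig_pos <- which(keep) - 1L                     # 0-based
  # biallelic segregating sites only
  biall <- apply(m, 2L, function(col) length(unique(col)) == 2L)
  m <- m[, biall, drop = FALSE]
  pos <- orig_pos[biall]
  S <- ncol(m)
  empty <- list(rmin = 0L,
                breakpoints = data.frame(start = integer(),
                                         end = integer()),
                n_incompatible_pairs = 0L)
  if (S < 2L || nrow(m) < 4L) return(empty)
  ints <- list()
  for (i in seq_len(S - 1L)) {
    for (j in seq.int(i + 1L, S)) {
      if (incompatible(m[, i], m[, j])) {
        ints[[length(ints) + 1L]] <- c(pos[i], pos[j])
      }
    }
  }
  if (length(ints) == 0L) return(empty)
  iv <- do.call(rbind, ints)
  sel <- greedy_disjoint(iv)
  list(rmin = nrow(sel),
       breakpoints = data.frame(start = sel[, 1L] + 1L, end = sel[, 2L]),
       n_incompatible_pairs = nrow(iv))
}

# maximum set of pairwise non-overlapping open intervals (a, b): scan by
# right endpoint, accept when the interval starts at or after the last
# accepted right endpoint (open intervals sharing an endpoint are disjoint)
greedy_disjoint <- function(iv) {
  iv <- iv[order(iv[, 2L], iv[, 1L]), , drop = FALSE]
  sel <- matrix(numeric(), 0L, 2L)
  last <- -Inf
  for (r in seq_len(nrow(iv))) {
    if (iv[r, 1L] >= last) {
      sel <- rbind(sel, iv[r, ])
      last <- iv[r, 2L]
    }
  }
  sel
}

#' Per-gene recombination and diversity statistics
#'
#' Combines [nucleotide_diversity()] and [rmin()] on one gene alignment into
#' the row format the regression consumes.
#'
#' @param gene_id label for the gene.
#' @param aln a nucleotide `haplotype_alignment` of the gene.
#' @return data.frame row: `gene_id`, `n` (sequences), `L` (gap-filtered
#'   length), `S`, `pi`, `rmin`, `rmin_per_nt`.
#' @export
gene_stats <- function(gene_id, aln) {
  div <- nucleotide_diversity(aln)
  rm <- rmin(aln)
  data.frame(gene_id = gene_id, n = n_samples(aln), L = div$L, S = div$S,
             pi = div$pi, rmin = rm$rmin, rmin_per_nt = rm$rmin / div$L,
             stringsAsFactors = FALSE)
}

#' Diversity-controlled regression of recombination intensity
#'
#' Ordinary least squares of the per-gene minimum recombination events per
#' nucleotide on nucleotide diversity (x1) and the number of aligned
#' sequences (x2): `y = b0 + b1 x1 + b2 x2 + e`. The residual e_i is the
#' per-gene recombination intensity after accounting for diversity and
#' sample size. If x2 is constant the design is rank-deficient; x2 is then
#' dropped with a warning and the model refit on x1 alone.
#'
#' @param stats data.frame with columns `gene_id`, `pi`, `n`,
#'   `rmin_per_nt` (rows from [gene_stats()]).
#' @return object of class `regression_fit`: list with `beta0`, `beta1`,
#'   `beta2` (`NA` if x2 dropped), `residuals` (named by gene),
#'   `r_squared`, `line_at_mean_n` (function of pi), `mean_n`, `model`
#'   (the underlying `lm`).
#' @export
regress <- function(stats) {
  if (nrow(stats) < 4L) stop("need at least 4 genes", call. = FALSE)
  drop_x2 <- length(unique(stats$n)) == 1L
  if (drop_x2) {
    warning("number of sequences is constant; dropping x2 from the design",
            call. = FALSE)
    fit <- stats::lm(rmin_per_nt ~ pi, data = stats)
    beta2 <- NA_real_
  } else {
    fit <- stats::lm(rmin_per_nt ~ pi + n, data = stats)
    beta2 <- unname(stats::coef(fit)["n"])
  }
  co <- stats::coef(fit)
  mean_n <- mean(stats$n)
  b0 <- unname(co["(Intercept)"]); b1 <- unname(co["pi"])
  line <- function(pi) {
    b0 + b1 * pi + if (is.na(beta2)) 0 else beta2 * mean_n
  }
  structure(list(beta0 = b0, beta1 = b1, beta2 = beta2,
                 residuals = stats::setNames(stats::residuals(fit),
                                             stats$gene_id),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 line_at_mean_n = line, mean_n = mean_n, model = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit: y = %.4g + %.4g*pi%s (R^2 = %.3f)\n",
              x$beta0, x$beta1,
              if (is.na(x$beta2)) "" else sprintf(" + %.4g*n", x$beta2),
              x$r_squared))
  invisible(x)
}

#' Per-gene recombination-intensity report
#'
#' Tabulates each gene's observed and fitted values with raw and
#' standardized residuals; genes are ranked by |standardized residual| and
#' flagged as deviating when |z| > 2 - i.e. when their recombination
#' intensity departs from what diversity and sample size predict.
#'
#' @param stats the data.frame passed to [regress()].
#' @param fit the resulting `regression_fit`.
#' @return data.frame (one row per gene, ranked): `gene_id`, `rmin`,
#'   `rmin_per_nt`, `pi`, `n`, `residual`, `z`, `deviating`.
#' @export
intensity_report <- function(stats, fit) {
  res <- fit$residuals[stats$gene_id]
  sd_res <- stats::sd(res)
  # an essentially perfect fit leaves only floating-point noise: no gene
  # deviates in that case
  scale <- max(abs(stats$rmin_per_nt), 1e-300)
  z <- if (isTRUE(sd_res > 1e-10 * scale)) res / sd_res else
    rep(0, length(res))
  out <- data.frame(gene_id = stats$gene_id, rmin = stats$rmin,
                    rmin_per_nt = stats$rmin_per_nt, pi = stats$pi,
                    n = stats$n, residual = unname(res), z = unname(z),
                    deviating = abs(unname(z)) > 2,
                    stringsAsFactors = FALSE)
  out[order(-abs(out$z)), , drop = FALSE]
}

#' Regression scatter of recombination intensity versus diversity
#'
#' @param stats,fit as for [intensity_report()].
#' @param ... passed to [plot()].
#' @return invisibly, `NULL`.
#' @export
plot_regression <- function(stats, fit, ...) {
  plot(stats$pi, stats$rmin_per_nt, xlab = "nucleotide diversity (pi)",
       ylab = "rmin per nucleotide", pch = 19, ...)
  xs <- seq(min(stats$pi), max(stats$pi), length.out = 100)
  graphics::lines(xs, vapply(xs, fit$line_at_mean_n, 0))
  invisible(NULL)
}

#' Write breakpoint intervals as a BED-like TSV
#'
#' @param gene_id gene label used in column 1.
#' @param rm result of [rmin()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_breakpoints <- function(gene_id, rm, path) {
  bed <- cbind(gene = gene_id, rm$breakpoints)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
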