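#' Per-recipient import fractions by donor population
#'
#' For recipient r and population P, the import fraction is the share of r's
#' expected chunks donated by members of P (excluding r itself), divided by
#' r's total expected chunks over all donors. Fractions over all donor
#' populations, the recipient's own included, sum to 1 per recipient; the
#' returned table keeps only rows with `donor_pop != recipient_pop` (the
#' cross-population flux view).
#'
#' @param cm a `coancestry_matrix` (or bare non-negative matrix with
#'   dimnames).
#' @param labels named character vector sample id -> population; every
#'   sample of `cm` must be labelled. Defaults to labels stored in `cm`.
#'   Pass fineSTRUCTURE cluster assignments here for subgroup-level flux.
#' @param denominator `"all"` (default; own-population chunks included in
#'   the denominator) or `"other"` (cross-population chunks only).
#' @param measure `"chunks"` (default): fractions of expected chunk
#'   *counts*, the co-ancestry heatmap's currency; or `"lengths"`:
#'   fractions of expected copied *sites*. Counts weight each copied
#'   segment equally and therefore emphasise recombination boundary events;
#'   lengths estimate the genome fraction copied from each population and
#'   are the measure of choice when recovering a planted migration
#'   fraction.
#' @return A `flux_table` data.frame with columns `recipient_id`,
#'   `recipient_pop`, `donor_pop`, `fraction`.
#' @export
import_fractions <- function(cm, labels = NULL,
                             denominator = c("all", "other"),
                             measure = c("chunks", "lengths")) {
  denominator <- match.arg(denominator)
  measure <- match.arg(measure)
  X <- if (inherits(cm, "coancestry_matrix")) {
    if (measure == "lengths") cm$lengths else cm$X
  } else cm
  if (measure == "lengths" && !inherits(cm, "coancestry_matrix")) {
    stop("measure = 'lengths' needs a coancestry_matrix object",
         call. = FALSE)
  }
  if (is.null(labels) && inherits(cm, "coancestry_matrix")) {
    labels <- cm$labels
  }
  samples <- rownames(X)
  if (is.null(labels) || !all(samples %in% names(labels))) {
    stop("every sample needs a population label", call. = FALSE)
  }
  pop <- labels[samples]
  pops <- sort(unique(pop))
  rows <- list()
  for (r in seq_along(samples)) {
    x <- X[r, ]
    x[r] <- 0
    total <- sum(x)
    if (total <= 0) {
      stop("recipient ", samples[r], " has zero total chunk count",
           call. = FALSE)
    }
    by_pop <- vapply(pops, function(p) sum(x[pop == p]), numeric(1))
    denom <- if (denominator == "all") total else
      total - by_pop[pop[r]]
    if (denom <= 0) {
      stop("recipient ", samples[r],
           " has no cross-population chunks (denominator = 'other')",
           call. = FALSE)
    }
    other <- setdiff(pops, pop[r])
    if (length(other) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        recipient_id = samples[r], recipient_pop = unname(pop[r]),
        donor_pop = other, fraction = unname(by_pop[other] / denom),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("flux_table", "data.frame")
  out
}

#' Slice a flux table and summarize with the median
#'
#' The same table answers import questions (fix the recipient populations)
#' and export questions (fix the donor populations): each row is one
#' recipient x donor-population fraction, so an export slice is simply the
#' transposed bookkeeping of the import slice.
#'
#' @param table a `flux_table` from [import_fractions()].
#' @param recipient_pops,donor_pops character vectors selecting rows; `NULL`
#'   keeps all.
#' @return list with `values` (selected fractions), `median`, and `n`.
#' @export
group_flux <- function(table, recipient_pops = NULL, donor_pops = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(recipient_pops)) {
    keep <- keep & table$recipient_pop %in% recipient_pops
  }
  if (!is.null(donor_pops)) keep <- keep & table$donor_pop %in% donor_pops
  vals <- table$fraction[keep]
  if (length(vals) == 0L) stop("empty flux selection", call. = FALSE)
  list(values = vals, median = stats::median(vals), n = length(vals))
}

#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Exact p-value by the null distribution of the rank sum whenever the
#' combined sample is small (`n1 + n2 <= 20`) and untied; otherwise the
#' normal approximation with tie correction and continuity correction. The
#' exact null is evaluated by dynamic programming over rank subsets, which
#' agrees with full enumeration of all `choose(n1+n2, n1)` assignments.
#'
#' @param a,b numeric vectors (n >= 1 each).
#' @return list of class `wilcoxon_result`: `statistic` (rank sum W of `a`,
#'   minus its minimum, i.e. the Mann-Whitney U), `p_two_sided`, `method`
#'   (`"exact"` or `"normal_approx"`), `n1`, `n2`, `medians`.
#' @export
ranksum_test <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  n1 <- length(a); n2 <- length(b)
  ranks <- rank(c(a, b))
  W <- sum(ranks[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0L
  if (length(unique(c(a, b))) == 1L) {
    warning("all values identical; p = 1", call. = FALSE)
    return(structure(list(statistic = U, p_two_sided = 1,
                          method = "degenerate", n1 = n1, n2 = n2,
                          medians = c(stats::median(a), stats::median(b))),
                     class = "wilcoxon_result"))
  }
  if (!has_ties && n1 + n2 <= 20L) {
    p <- exact_u_pvalue(U, n1, n2)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * (N + 1 - tie_term)
    zn <- U - mu
    z <- (zn - sign(zn) * 0.5) / sqrt(sigma2)    # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(statistic = U, p_two_sided = p, method = method,
                 n1 = n1, n2 = n2,
                 medians = c(stats::median(a), stats::median(b))),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: U = %g, p = %.4g (%s; n1 = %d, n2 = %d)\n",
              x$statistic, x$p_two_sided, x$method, x$n1, x$n2))
  invisible(x)
}

# exact two-sided p for the Mann-Whitney U under the untied null:
# counts of rank subsets by U via the standard Gaussian-binomial recurrence
exact_u_pvalue <- function(U, n1, n2) {
  max_u <- n1 * n2
  # f[u+1] = number of ways to choose n1 of n1+n2 ranks with U statistic u
  f <- u_null_counts(n1, n2)
  total <- choose(n1 + n2, n1)
  u_obs <- round(U)
  # two-sided: double the smaller tail (U symmetric about n1 n2 / 2)
  lo <- min(u_obs, max_u - u_obs)
  p <- 2 * sum(f[seq_len(lo + 1L)]) / total
  min(p, 1)
}

# null distribution of U: subset-count DP over rank sums. dp[j+1, w+1] =
# number of n1-subsets of ranks 1..N with j elements summing to w; U is the
# rank sum shifted by its minimum.
u_null_counts <- function(n1, n2) {
  N <- n1 + n2
  max_w <- sum(seq.int(N - n1 + 1L, N))
  dp <- matrix(0, n1 + 1L, max_w + 1L)
  dp[1L, 1L] <- 1
  for (r in seq_len(N)) {
    for (j in seq.int(min(n1, r), 1L)) {
      w_to <- seq.int(r, max_w)
      dp[j + 1L, w_to + 1L] <- dp[j + 1L, w_to + 1L] +
        dp[j, w_to - r + 1L]
    }
  }
  w_counts <- dp[n1 + 1L, ]
  min_w <- n1 * (n1 + 1L) / 2
  # f[u + 1] for u = 0..n1*n2
  w_counts[seq.int(min_w + 1L, min_w + n1 * n2 + 1L)]
}

#' Write a flux table as TSV
#' @param table a `flux_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flux_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
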