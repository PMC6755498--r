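#' Parameters of the haplotype-copying model
#'
#' The copying (chromosome painting) HMM models a recipient haplotype as a
#' mosaic copied from a panel of donor haplotypes. Between adjacent SNPs at
#' alignment distance d the donor identity switches with probability
#' `1 - exp(-switch_scale * d)`; conditional on a switch the new donor is
#' uniform over the panel. At each SNP the recipient allele matches the
#' current donor's allele with probability `1 - miscopy` and mismatches with
#' probability `miscopy`.
#'
#' @param switch_scale positive real; expected switch intensity per bp.
#' @param miscopy per-site emission mismatch probability, in (0, 0.5).
#' @return list of class `painting_params`.
#' @export
painting_params <- function(switch_scale, miscopy) {
  if (!is.numeric(switch_scale) || switch_scale <= 0) {
    stop("switch_scale must be > 0", call. = FALSE)
  }
  if (!is.numeric(miscopy) || miscopy <= 0 || miscopy >= 0.5) {
    stop("miscopy must lie in (0, 0.5)", call. = FALSE)
  }
  structure(list(switch_scale = switch_scale, miscopy = miscopy),
            class = "painting_params")
}

#' Default copying-model parameters from the data
#'
#' The miscopy rate follows the Watterson-style convention
#' `theta_w / (theta_w + 2k)` with `theta_w = 1 / sum_{i<k} 1/i` for a panel
#' of k donors, clipped to (1e-4, 0.49). The switch scale is set so the
#' expected number of donor switches across the painted region is about 10
#' (`switch_scale = 10 / total inter-SNP distance`), a weakly informative
#' default for mosaic genomes; both values can be overridden.
#'
#' @param snps a `snp_haplotypes`.
#' @param switch_scale,miscopy optional overrides; if supplied they are
#'   echoed unchanged.
#' @return a `painting_params`.
#' @export
estimate_params <- function(snps, switch_scale = NULL, miscopy = NULL) {
  stopifnot(inherits(snps, "snp_haplotypes"))
  n <- nrow(snps$matrix)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  k <- n - 1L                               # leave-one-out donor panel size
  if (is.null(miscopy)) {
    theta_w <- if (k >= 2L) 1 / sum(1 / seq_len(k - 1L)) else 1
    miscopy <- theta_w / (theta_w + 2 * k)
    miscopy <- min(max(miscopy, 1e-4), 0.49)
  }
  if (is.null(switch_scale)) {
    total <- sum(snps$distances)
    switch_scale <- if (total > 0) 10 / total else 1e-3
  }
  painting_params(switch_scale, miscopy)
}

#' Paint one recipient haplotype against a leave-one-out donor panel
#'
#' Runs scaled forward-backward under the copying HMM with the recipient's
#' own row excluded from the donor panel. Returns the per-site copy
#' posterior (rows sum to 1 over donors) and the expected number of maximal
#' copied segments ("chunks") attributed to each donor: the initial
#' assignment counts as one chunk, and each posterior donor-changing switch
#' adds expected fractional chunks.
#'
#' @param snps a `snp_haplotypes` with N >= 2 samples and L >= 1 SNPs.
#' @param recipient index (1-based) or sample id of the recipient.
#' @param params a `painting_params`.
#' @return list with `expected_chunks` (named vector over donors),
#'   `copy_posterior` (L x k matrix), `expected_lengths` (named vector:
#'   expected number of SNPs copied from each donor), and `log_lik`.
#' @export
paint_recipient <- function(snps, recipient, params) {
  stopifnot(inherits(snps, "snp_haplotypes"),
            inherits(params, "painting_params"))
  ids <- rownames(snps$matrix)
  if (is.character(recipient)) recipient <- match(recipient, ids)
  if (is.na(recipient) || recipient < 1L || recipient > nrow(snps$matrix)) {
    stop("unknown recipient", call. = FALSE)
  }
  L <- ncol(snps$matrix)
  donors <- setdiff(seq_len(nrow(snps$matrix)), recipient)
  k <- length(donors)
  if (k == 0L) stop("no donors available", call. = FALSE)
  if (L == 0L) stop("no SNPs to paint", call. = FALSE)

  rec <- snps$matrix[recipient, ]
  H <- snps$matrix[donors, , drop = FALSE]        # k x L donor alleles
  # emission matrix e[l, j]: match -> 1-miscopy, mismatch -> miscopy
  match_mat <- t(H) == rec                        # L x k
  e <- ifelse(match_mat, 1 - params$miscopy, params$miscopy)

  s <- 1 - exp(-params$switch_scale * snps$distances)   # length L-1

  # scaled forward
  fwd <- matrix(0, L, k)
  scale <- numeric(L)
  a <- e[1L, ] / k
  scale[1L] <- sum(a)
  fwd[1L, ] <- a / scale[1L]
  if (L > 1L) {
    for (l in seq_len(L - 1L)) {
      # T(c,d) = (1-s) 1[c=d] + s/k  => column sums decompose
      a <- ((1 - s[l]) * fwd[l, ] + s[l] / k) * e[l + 1L, ]
      scale[l + 1L] <- sum(a)
      fwd[l + 1L, ] <- a / scale[l + 1L]
    }
  }
  # scaled backward
  bwd <- matrix(0, L, k)
  bwd[L, ] <- 1
  if (L > 1L) {
    for (l in seq.int(L - 1L, 1L)) {
      v <- e[l + 1L, ] * bwd[l + 1L, ]
      bwd[l, ] <- ((1 - s[l]) * v + s[l] * sum(v) / k) / scale[l + 1L]
    }
  }
  post <- fwd * bwd
  post <- post / rowSums(post)

  # expected donor-changing switches: P(z_l != d, z_{l+1} = d)
  chunks <- post[1L, ]
  exp_len <- colSums(post)
  if (L > 1L) {
    for (l in seq_len(L - 1L)) {
      # joint P(z_l=c, z_{l+1}=d) = fwd_l(c) T(c,d) e_{l+1}(d) bwd_{l+1}(d)/scale_{l+1}
      # sum over c != d of the s/k part only (the stay part has c = d)
      into <- (s[l] / k) * (1 - fwd[l, ]) * e[l + 1L, ] * bwd[l + 1L, ] /
        scale[l + 1L]
      chunks <- chunks + into
    }
  }
  names(chunks) <- ids[donors]
  names(exp_len) <- ids[donors]
  colnames(post) <- ids[donors]
  list(expected_chunks = chunks, copy_posterior = post,
       expected_lengths = exp_len, log_lik = sum(log(scale)))
}

#' Co-ancestry matrix by painting every sample
#'
#' Paints each sample as recipient against all others (leave-one-out) and
#' assembles the N x N matrix of expected chunk counts: entry `[r, d]` is
#' the expected number of chunks recipient r copied from donor d; the
#' diagonal is zero. Deterministic given inputs.
#'
#' @param snps a `snp_haplotypes` with N >= 3.
#' @param params a `painting_params`; defaults to [estimate_params()].
#' @return object of class `coancestry_matrix`: list with `X` (chunk
#'   counts), `lengths` (expected copied SNPs, same shape), `samples`,
#'   `labels`, `params`.
#' @export
coancestry <- function(snps, params = estimate_params(snps)) {
  stopifnot(inherits(snps, "snp_haplotypes"))
  n <- nrow(snps$matrix)
  if (n < 3L) stop("need at least 3 samples for a donor panel of >= 2",
                   call. = FALSE)
  ids <- rownames(snps$matrix)
  X <- matrix(0, n, n, dimnames = list(ids, ids))
  Len <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(n)) {
    p <- paint_recipient(snps, r, params)
    X[r, names(p$expected_chunks)] <- p$expected_chunks
    Len[r, names(p$expected_lengths)] <- p$expected_lengths
  }
  structure(list(X = X, lengths = Len, samples = ids,
                 labels = snps$labels, params = params),
            class = "coancestry_matrix")
}

#' @export
print.coancestry_matrix <- function(x, ...) {
  cat(sprintf("coancestry_matrix: %d samples, mean chunks/recipient %.2f\n",
              length(x$samples), mean(rowSums(x$X))))
  invisible(x)
}

#' Write a co-ancestry matrix as TSV (rows = recipients, columns = donors)
#'
#' @param cm a `coancestry_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coancestry <- function(cm, path) {
  utils::write.table(
    cbind(recipient = rownames(cm$X), as.data.frame(cm$X)), path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Co-ancestry heatmap
#'
#' @param cm a `coancestry_matrix`.
#' @param ... passed to [stats::heatmap()].
#' @return invisibly, the heatmap object.
#' @export
plot_coancestry <- function(cm, ...) {
  invisible(stats::heatmap(cm$X, Rowv = NA, Colv = NA, scale = "none",
                           xlab = "donor", ylab = "recipient", ...))
}
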