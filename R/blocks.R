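#' Contiguous physical block scheme for the jackknife
#'
#' Assigns every SNP to a contiguous block of at most `block_span` bp within
#' its chromosome. Blocks are the resampling unit of the weighted block
#' jackknife; the default span of 5 Mb is recorded with every result so that
#' standard errors are always interpretable under a stated scheme.
#'
#' @param snp SNP table (as in [geno_matrix()]) or a `geno_matrix`.
#' @param block_span Block length in bp (default 5e6).
#' @return Integer vector of block ids (1..g, only non-empty blocks
#'   numbered), with the scheme description in attribute `scheme`.
#' @export
block_scheme <- function(snp, block_span = 5e6) {
  if (inherits(snp, "geno_matrix")) snp <- snp$snp
  raw <- paste0(snp$chrom, ":", (snp$physical_pos - 1) %/% block_span)
  ids <- match(raw, unique(raw))
  attr(ids, "scheme") <- paste0("contiguous ", format(block_span, scientific = FALSE),
                                "bp physical blocks")
  ids
}

# Weighted delete-one-block jackknife (Busing-style) for unequal block sizes.
# theta_full: estimate on all n observations; theta_loo: leave-one-block-out
# estimates; m: block sizes. SE^2 = (1/g) sum_j (tau_j - tau_bar)^2 / (h_j-1)
# with h_j = n/m_j, pseudovalues tau_j = h_j theta - (h_j-1) theta_loo_j and
# tau_bar the weighted-jackknife point estimate.
jackknife_se <- function(theta_full, theta_loo, m) {
  g <- length(theta_loo)
  if (g < 2) stop_pk("block jackknife needs at least 2 non-empty blocks")
  stopifnot(length(m) == g)
  n <- sum(m)
  h <- n / m
  tau <- h * theta_full - (h - 1) * theta_loo
  tau_bar <- g * theta_full - sum((1 - m / n) * theta_loo)
  sqrt(sum((tau - tau_bar)^2 / (h - 1)) / g)
}

#' Weighted block-jackknife standard error of a statistic
#'
#' Recomputes the statistic with each block deleted and combines the
#' leave-one-out estimates with block-size weights, so unequal blocks (e.g.
#' uneven SNP counts in physical windows) are handled correctly. For the
#' mean of iid values in singleton blocks this reduces exactly to the
#' classical standard error of the mean.
#'
#' @param values Per-observation contributions, or `NULL` when `statistic`
#'   is supplied.
#' @param blocks Integer block id per observation (see [block_scheme()]).
#' @param statistic Optional function `f(keep_index) -> scalar` recomputing
#'   the statistic on a subset of observations; defaults to the mean of
#'   `values`.
#' @return A list with `estimate`, `se`, `n_blocks`, `n`.
#' @export
block_jackknife <- function(values = NULL, blocks, statistic = NULL) {
  blocks <- as.integer(factor(blocks))
  g <- max(blocks)
  if (g < 2) stop_pk("block jackknife needs at least 2 non-empty blocks")
  n <- length(blocks)
  m <- tabulate(blocks, g)
  if (is.null(statistic)) {
    stopifnot(length(values) == n)
    tot <- sum(values)
    bs <- rowsum(values, blocks)[, 1]
    est <- tot / n
    loo <- (tot - bs) / (n - m)
  } else {
    est <- statistic(seq_len(n))
    loo <- vapply(seq_len(g), function(b) statistic(which(blocks != b)), numeric(1))
  }
  list(estimate = est, se = jackknife_se(est, loo, m), n_blocks = g, n = n)
}

# Jackknife for a ratio-of-sums statistic sum(num)/sum(den), from per-block
# sums. Returns estimate, SE, leave-one-out values.
jackknife_ratio <- function(num_b, den_b, m) {
  tot_n <- sum(num_b); tot_d <- sum(den_b)
  if (tot_d == 0) stop_pk("denominator is zero over all SNPs")
  est <- tot_n / tot_d
  loo <- (tot_n - num_b) / (tot_d - den_b)
  loo[!is.finite(loo)] <- est
  list(estimate = est, se = jackknife_se(est, loo, m), loo = loo)
}
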