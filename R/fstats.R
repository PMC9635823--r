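fstat_result <- function(stat, pops, estimate, se, n_snps, n_blocks) {
  z <- if (se > 0) estimate / se else ifelse(estimate == 0, 0, sign(estimate) * Inf)
  tibble(
    statistic = stat,
    pops = paste(pops, collapse = ","),
    estimate = estimate,
    se = se,
    z = z,
    p = 2 * pnorm(-abs(z)),
    n_snps = n_snps,
    n_blocks = n_blocks
  )
}

get_freq_cols <- function(freqs, pops) {
  missing_p <- setdiff(pops, freqs$groups)
  if (length(missing_p) > 0) stop_pk("unknown populations: ", paste(missing_p, collapse = ", "))
  freqs$p[, pops, drop = FALSE]
}

#' Outgroup f3-statistic
#'
#' `f3(O; A, B) = mean over SNPs of (p_O - p_A)(p_O - p_B)`, the shared
#' genetic drift of A and B relative to the outgroup O. SNPs where any of the
#' three populations lacks data are skipped (per-statistic SNP sets), and the
#' standard error comes from a weighted block jackknife over contiguous
#' physical blocks. No small-sample heterozygosity correction is applied by
#' default: on pseudo-haploid data comparability across pairs matters more
#' than absolute scale.
#'
#' @param freqs A `freq_table` from [allele_freqs()].
#' @param outgroup,a,b Population labels.
#' @param block_span Jackknife block length in bp.
#' @return One-row tibble with estimate, jackknife `se`, `z`, normal `p`,
#'   `n_snps`, `n_blocks`.
#' @export
f3_outgroup <- function(freqs, outgroup, a, b, block_span = 5e6) {
  pm <- get_freq_cols(freqs, c(outgroup, a, b))
  use <- complete.cases(pm)
  if (!any(use)) {
    stop_pk("no SNP has data in all of ", outgroup, ", ", a, ", ", b)
  }
  term <- (pm[use, 1] - pm[use, 2]) * (pm[use, 1] - pm[use, 3])
  blocks <- block_scheme(freqs$snp[use, ], block_span)
  jk <- block_jackknife(term, blocks)
  fstat_result("f3", c(outgroup, a, b), jk$estimate, jk$se, jk$n, jk$n_blocks)
}

#' Plain f4-statistic
#'
#' `f4(A, B; C, D) = mean over SNPs of (p_A - p_B)(p_C - p_D)`.
#'
#' @inheritParams f3_outgroup
#' @param a,b,c,d Population labels.
#' @return One-row tibble as in [f3_outgroup()].
#' @export
f4_statistic <- function(freqs, a, b, c, d, block_span = 5e6) {
  pm <- get_freq_cols(freqs, c(a, b, c, d))
  use <- complete.cases(pm)
  if (!any(use)) stop_pk("no SNP has data in all four populations")
  term <- (pm[use, 1] - pm[use, 2]) * (pm[use, 3] - pm[use, 4])
  blocks <- block_scheme(freqs$snp[use, ], block_span)
  jk <- block_jackknife(term, blocks)
  fstat_result("f4", c(a, b, c, d), jk$estimate, jk$se, jk$n, jk$n_blocks)
}

#' D-statistic (ABBA-BABA)
#'
#' `D(W, X; Y, Z)` is the normalized four-population test of treeness,
#' estimated as
#' `sum (p_W - p_X)(p_Y - p_Z) / sum (p_W + p_X - 2 p_W p_X)(p_Y + p_Z - 2 p_Y p_Z)`
#' over SNPs with data in all four populations, with the standard error from
#' a weighted block jackknife of the ratio.
#'
#' @inheritParams f3_outgroup
#' @param w,x,y,z Population labels.
#' @return One-row tibble as in [f3_outgroup()].
#' @export
d_statistic <- function(freqs, w, x, y, z, block_span = 5e6) {
  pm <- get_freq_cols(freqs, c(w, x, y, z))
  use <- complete.cases(pm)
  if (!any(use)) stop_pk("no SNP has data in all four populations")
  pw <- pm[use, 1]; px <- pm[use, 2]; py <- pm[use, 3]; pz <- pm[use, 4]
  num <- (pw - px) * (py - pz)
  den <- (pw + px - 2 * pw * px) * (py + pz - 2 * py * pz)
  blocks <- as.integer(factor(block_scheme(freqs$snp[use, ], block_span)))
  g <- max(blocks)
  if (g < 2) stop_pk("need at least 2 jackknife blocks")
  m <- tabulate(blocks, g)
  jk <- jackknife_ratio(rowsum(num, blocks)[, 1], rowsum(den, blocks)[, 1], m)
  fstat_result("D", c(w, x, y, z), jk$estimate, jk$se, sum(m), g)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector; input order
#' is preserved.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop_pk("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pairwise (1 - f3) dissimilarity matrix
#'
#' Computes outgroup f3 for every pair of individuals (each treated as a
#' population of one) and returns `1 - f3` as a genetic dissimilarity, the
#' distance used for MDS and isolation-by-distance. Pairs whose count of
#' jointly usable SNPs falls below `min_overlap` are masked (`NA`); the
#' diagonal is 0.
#'
#' @param g A [geno_matrix()].
#' @param outgroup Population label (from `g$ind$population`) or character
#'   vector of individual ids used as the outgroup.
#' @param individuals Ids to include; default all non-outgroup individuals.
#' @param min_overlap Minimum jointly usable SNPs per pair (default 2000,
#'   the panel-overlap filter applied throughout).
#' @return A `pk_f3_matrix`: list with matrices `dist` (1 - f3, masked pairs
#'   `NA`), `f3`, `overlap`, the ids, and `min_overlap`.
#' @export
pairwise_f3_matrix <- function(g, outgroup, individuals = NULL, min_overlap = 2000) {
  stopifnot(inherits(g, "geno_matrix"))
  og_ids <- if (all(outgroup %in% g$ind$population) && !all(outgroup %in% g$ind$id)) {
    g$ind$id[g$ind$population %in% outgroup]
  } else outgroup
  if (length(og_ids) == 0) stop_pk("no outgroup individuals found")
  individuals <- individuals %||% setdiff(g$ind$id, og_ids)

  fo <- allele_freqs(subset_geno(g, inds = og_ids),
                     grouping = setNames(rep("O", length(og_ids)), og_ids))
  p_o <- fo$p[, "O"]
  fi <- allele_freqs(subset_geno(g, inds = individuals), grouping = "individual")
  pm <- fi$p[, individuals, drop = FALSE]

  ok_o <- !is.na(p_o)
  M <- (p_o - pm)[ok_o, , drop = FALSE]
  V <- !is.na(M)
  M0 <- M
  M0[!V] <- 0
  num <- crossprod(M0)
  cnt <- crossprod(V * 1)
  f3 <- num / cnt
  f3[cnt == 0] <- NA_real_
  d <- 1 - f3
  d[cnt < min_overlap] <- NA_real_
  diag(d) <- 0
  structure(list(dist = d, f3 = f3, overlap = cnt, ids = individuals,
                 min_overlap = min_overlap),
            class = "pk_f3_matrix")
}

#' @export
print.pk_f3_matrix <- function(x, ...) {
  n <- length(x$ids)
  masked <- sum(is.na(x$dist[upper.tri(x$dist)]))
  cat("<pk_f3_matrix> ", n, " individuals, ", n * (n - 1) / 2, " pairs (",
      masked, " masked below ", x$min_overlap, " overlapping SNPs)\n", sep = "")
  invisible(x)
}

#' @export
tidy.pk_f3_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$dist), arr.ind = TRUE)
  tibble(
    id1 = x$ids[idx[, 1]],
    id2 = x$ids[idx[, 2]],
    f3 = x$f3[idx],
    dist = x$dist[idx],
    n_overlap = as.integer(x$overlap[idx]),
    masked = is.na(x$dist[idx])
  )
}
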