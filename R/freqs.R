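#' Per-group allele frequencies
#'
#' Computes, for every SNP and every group, the frequency of `allele1` and
#' the number of observed allele copies. Diploid calls contribute two allele
#' copies, pseudo-haploid and hemizygous calls contribute one, so a single
#' pseudo-haploid individual is a population of one allele per site.
#'
#' @param g A [geno_matrix()].
#' @param grouping How individuals map to populations: `NULL` uses the
#'   `population` column of `g$ind`; `"individual"` treats every individual
#'   as its own group; otherwise a named character vector `id -> group` or a
#'   data frame with columns `id`, `group`. Individuals left unmapped are
#'   dropped.
#' @return A `freq_table`: list with matrices `p` (frequency, `NA` where the
#'   group has no data) and `n` (allele counts), the SNP table, and the group
#'   labels.
#' @export
allele_freqs <- function(g, grouping = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  ids <- g$ind$id
  if (is.null(grouping)) {
    grp <- g$ind$population
  } else if (identical(grouping, "individual")) {
    grp <- ids
  } else if (is.data.frame(grouping)) {
    grp <- grouping$group[match(ids, grouping$id)]
  } else {
    grp <- unname(grouping[ids])
  }
  keep <- !is.na(grp)
  dw <- dosage_weights(g)
  p <- dw$p[, keep, drop = FALSE]
  w <- dw$w[, keep, drop = FALSE]
  grp <- grp[keep]
  groups <- unique(grp)
  gidx <- match(grp, groups)
  copies <- p * w
  copies[is.na(copies)] <- 0
  # column-group sums via matrix multiply with an indicator matrix
  G <- matrix(0, nrow = length(grp), ncol = length(groups))
  G[cbind(seq_along(gidx), gidx)] <- 1
  num <- copies %*% G
  den <- w %*% G
  freq <- num / den
  freq[den == 0] <- NA_real_
  colnames(freq) <- colnames(den) <- groups
  structure(list(p = freq, n = den, snp = g$snp, groups = groups),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("<freq_table> ", nrow(x$p), " SNPs x ", length(x$groups), " groups: ",
      paste(head(x$groups, 8), collapse = " "),
      if (length(x$groups) > 8) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.freq_table <- function(x, ...) {
  tibble(
    snp_id = rep(x$snp$snp_id, times = length(x$groups)),
    group = rep(x$groups, each = nrow(x$p)),
    p = as.vector(x$p),
    n = as.vector(x$n)
  )
}
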