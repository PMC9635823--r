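#' Random-haploid calling from per-site base observations
#'
#' Emulates pseudo-haploid genotyping of low-coverage data: at every panel
#' site one observed base is drawn uniformly from the individual's pileup
#' list and treated as a homozygous haploid call — 2 copies of allele1 if it
#' matches allele1, 0 if it matches allele2, missing if it matches neither
#' or no base was observed.
#'
#' @param pileup Data frame with columns `individual`, `chrom`, `pos`,
#'   `bases` (string of observed bases, e.g. `"ACCA"`; empty = no coverage).
#' @param snp SNP panel table (as in [geno_matrix()]).
#' @param seed Optional integer seed for the allele draws.
#' @return A pseudo-haploid [geno_matrix()]; the number of draws discarded
#'   because they matched neither allele is in attribute `n_nonmatching`.
#' @export
random_haploid_call <- function(pileup, snp, seed = NULL) {
  pileup <- as_tibble(pileup)
  inds <- unique(pileup$individual)
  key_panel <- paste(snp$chrom, snp$physical_pos)
  calls <- matrix(NA_integer_, nrow = nrow(snp), ncol = length(inds))
  n_nonmatching <- 0L
  with_seed(seed, {
    for (j in seq_along(inds)) {
      pu <- pileup[pileup$individual == inds[j], ]
      row <- match(paste(pu$chrom, pu$pos), key_panel)
      ok <- !is.na(row) & nzchar(pu$bases)
      if (!any(ok)) next
      drawn <- vapply(pu$bases[ok], function(b) {
        chars <- strsplit(b, "", fixed = TRUE)[[1]]
        chars[sample.int(length(chars), 1)]
      }, character(1), USE.NAMES = FALSE)
      r <- row[ok]
      call <- ifelse(drawn == snp$allele1[r], 2L,
                     ifelse(drawn == snp$allele2[r], 0L, NA_integer_))
      n_nonmatching <- n_nonmatching + sum(is.na(call))
      calls[r, j] <- call
    }
  })
  g <- geno_matrix(calls, snp,
                   tibble(id = inds, sex = "U", population = inds,
                          pseudo_haploid = TRUE))
  if (n_nonmatching > 0) {
    inform(paste0(n_nonmatching, " drawn bases matched neither panel allele; set missing"))
  }
  attr(g, "n_nonmatching") <- n_nonmatching
  g
}

#' Minor-allele-frequency panel filter
#'
#' Keeps biallelic SNPs whose minor-allele frequency, computed in a
#' designated panel of individuals, strictly exceeds `maf` (default 10%, the
#' panel-construction rule used throughout). SNPs with no called allele in
#' the panel are dropped and counted. The filter is idempotent.
#'
#' @param g A [geno_matrix()].
#' @param panel_ids Individual ids defining the frequency panel.
#' @param maf MAF threshold; SNPs with panel MAF `<= maf` are removed.
#' @return Filtered `geno_matrix`, with a `filter_report` attribute giving
#'   removed counts.
#' @export
filter_maf_biallelic <- function(g, panel_ids, maf = 0.10) {
  stopifnot(inherits(g, "geno_matrix"))
  missing_ids <- setdiff(panel_ids, g$ind$id)
  if (length(missing_ids) > 0) stop_pk("panel ids absent: ", paste(missing_ids, collapse = ", "))
  fr <- allele_freqs(subset_geno(g, inds = panel_ids),
                     grouping = setNames(rep("panel", length(panel_ids)), panel_ids))
  p <- fr$p[, "panel"]
  n <- fr$n[, "panel"]
  no_data <- n == 0
  maf_obs <- pmin(p, 1 - p)
  keep <- !no_data & maf_obs > maf
  keep[is.na(keep)] <- FALSE
  out <- subset_geno(g, snps = keep)
  attr(out, "filter_report") <- tibble(
    n_input = nrow(g$snp),
    n_kept = sum(keep),
    n_removed_maf = sum(!keep & !no_data),
    n_removed_no_data = sum(no_data)
  )
  out
}
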