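#' Genotype matrix container
#'
#' Holds a SNP-by-individual genotype matrix together with its SNP and sample
#' annotation. Calls count copies of `allele1` of the corresponding SNP
#' record: diploid calls are 0/1/2, pseudo-haploid and hemizygous calls are
#' encoded 0/2 (never 1), and `NA` is missing. This is the substrate of every
#' statistic in the package.
#'
#' @param calls Integer matrix, one row per SNP and one column per
#'   individual; values in `{0, 1, 2, NA}`.
#' @param snp Data frame with columns `snp_id`, `chrom`, `genetic_pos`,
#'   `physical_pos` (1-based bp), `allele1`, `allele2`, and optionally a
#'   logical `par` column masking pseudoautosomal X SNPs. Rows must be sorted
#'   by position within each chromosome.
#' @param ind Data frame with columns `id`, `sex` (`"M"`, `"F"` or `"U"`),
#'   `population`, and optionally a logical `pseudo_haploid` flag (default
#'   `TRUE`).
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, snp, ind) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  snp <- as_tibble(snp)
  ind <- as_tibble(ind)
  if (!all(c("snp_id", "chrom", "physical_pos", "allele1", "allele2") %in% names(snp))) {
    stop_pk("snp table must have snp_id, chrom, physical_pos, allele1, allele2")
  }
  if (!"genetic_pos" %in% names(snp)) snp$genetic_pos <- 0
  if (!all(c("id") %in% names(ind))) stop_pk("ind table must have an id column")
  if (!"sex" %in% names(ind)) ind$sex <- "U"
  if (!"population" %in% names(ind)) ind$population <- ind$id
  if (!"pseudo_haploid" %in% names(ind)) ind$pseudo_haploid <- TRUE
  if (nrow(snp) != nrow(calls)) {
    stop_pk("calls has ", nrow(calls), " rows but snp table has ", nrow(snp))
  }
  if (nrow(ind) != ncol(calls)) {
    stop_pk("calls has ", ncol(calls), " columns but ind table has ", nrow(ind))
  }
  if (anyDuplicated(ind$id)) stop_pk("duplicate individual ids")
  if (any(snp$physical_pos < 1, na.rm = TRUE)) stop_pk("physical_pos must be >= 1")
  if (any(snp$allele1 == snp$allele2)) stop_pk("allele1 must differ from allele2")
  rng <- suppressWarnings(range(calls, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0L || rng[2] > 2L)) {
    stop_pk("calls must be 0, 1, 2 or NA")
  }
  unsorted <- snp %>%
    group_by(.data$chrom) %>%
    summarise(ok = !is.unsorted(.data$physical_pos)) %>%
    filter(!.data$ok)
  if (nrow(unsorted) > 0) {
    stop_pk("SNPs not sorted by position on chromosome ", unsorted$chrom[1])
  }
  ph <- ind$pseudo_haploid
  if (any(ph)) {
    has_het <- colSums(calls[, ph, drop = FALSE] == 1L, na.rm = TRUE) > 0
    if (any(has_het)) {
      stop_pk("pseudo-haploid individual carries a heterozygous call: ",
              paste(ind$id[ph][has_het], collapse = ", "))
    }
  }
  colnames(calls) <- ind$id
  structure(list(calls = calls, snp = snp, ind = ind), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$snp), " SNPs x ", nrow(x$ind), " individuals\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$snp$chrom), collapse = " "), "\n", sep = "")
  cat("  pseudo-haploid: ", sum(x$ind$pseudo_haploid), "/", nrow(x$ind), "\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat("  missingness: ", sprintf("%.1f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(nrow(x$snp), nrow(x$ind))

#' Subset a genotype matrix
#'
#' @param g A [geno_matrix()].
#' @param snps Logical or integer index over SNP rows (optional).
#' @param inds Character ids, or logical/integer index over individuals
#'   (optional).
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(g, snps = NULL, inds = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (!is.null(snps)) {
    g$calls <- g$calls[snps, , drop = FALSE]
    g$snp <- g$snp[snps, ]
  }
  if (!is.null(inds)) {
    if (is.character(inds)) {
      missing_ids <- setdiff(inds, g$ind$id)
      if (length(missing_ids) > 0) stop_pk("unknown ids: ", paste(missing_ids, collapse = ", "))
      inds <- match(inds, g$ind$id)
    }
    g$calls <- g$calls[, inds, drop = FALSE]
    g$ind <- g$ind[inds, ]
  }
  geno_matrix(g$calls, g$snp, g$ind)
}

#' Restrict to autosomal or (non-pseudoautosomal) X SNPs
#'
#' X SNPs flagged in the optional `par` mask column are excluded from X
#' analyses; the pseudoautosomal boundaries are panel-specific and therefore
#' user-supplied.
#'
#' @param g A [geno_matrix()].
#' @param class `"autosomal"` or `"X"`.
#' @param exclude_par Drop PAR-masked X SNPs (default `TRUE`).
#' @return A `geno_matrix`.
#' @export
chrom_class_geno <- function(g, class = c("autosomal", "X"), exclude_par = TRUE) {
  class <- match.arg(class)
  on_x <- is_x_chrom(g$snp$chrom)
  if (class == "autosomal") return(subset_geno(g, snps = !on_x))
  keep <- on_x
  if (exclude_par && "par" %in% names(g$snp)) keep <- keep & !(g$snp$par %in% TRUE)
  subset_geno(g, snps = keep)
}

# Fraction-of-allele1 matrix (0/0.5/1, NA missing) and per-cell allele counts
# (2 for diploid autosomal or female-X calls, 1 for pseudo-haploid calls and
# male X). Used by every frequency computation.
dosage_weights <- function(g) {
  p <- g$calls / 2
  w <- matrix(2, nrow = nrow(g$snp), ncol = nrow(g$ind))
  ph <- g$ind$pseudo_haploid
  w[, ph] <- 1
  on_x <- is_x_chrom(g$snp$chrom)
  if (any(on_x)) {
    male <- g$ind$sex == "M"
    w[on_x, male] <- 1
  }
  w[is.na(p)] <- 0
  list(p = p, w = w)
}
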