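# Programmatic fixtures shared across the suite.

# Small SNP table: one "chromosome" per 10 Mb so block/window machinery has
# something to chew on.
toy_snp <- function(n, chrom = "1", spacing = 5e4, start = 1) {
  pos <- start + spacing * (seq_len(n) - 1)
  if (length(chrom) == 1 && n > 0 && max(pos) > 2e9) {
    # stay inside integer positions: roll over onto extra chromosomes
    part <- pos %/% 2e9
    chrom <- paste0(chrom, ".", part)
    pos <- pos %% 2e9 + 1
  }
  tibble::tibble(
    snp_id = paste0("rs", seq_len(n)),
    chrom = chrom,
    genetic_pos = 0,
    physical_pos = as.integer(pos),
    allele1 = "A",
    allele2 = "G"
  )
}

toy_geno <- function(calls, chrom = "1", sex = NULL, pseudo = NULL,
                     spacing = 5e4) {
  calls <- as.matrix(calls)
  n_ind <- ncol(calls)
  ids <- paste0("ind", seq_len(n_ind))
  if (is.null(pseudo)) pseudo <- !apply(calls == 1L, 2, any, na.rm = TRUE)
  geno_matrix(
    calls,
    toy_snp(nrow(calls), chrom = chrom, spacing = spacing),
    tibble::tibble(id = ids, sex = sex %||% rep("U", n_ind),
                   population = ids, pseudo_haploid = pseudo)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Hand-built frequency table (populations given as frequency columns),
# bypassing genotype sampling when a test needs exact population
# frequencies.
toy_freq_table <- function(p_mat, snp = NULL, n = NULL) {
  p_mat <- as.matrix(p_mat)
  # one chromosome per SNP so even tiny fixtures span >= 2 jackknife blocks
  snp <- snp %||% toy_snp(nrow(p_mat), chrom = as.character(seq_len(nrow(p_mat))),
                          spacing = 0)
  n <- n %||% matrix(100, nrow(p_mat), ncol(p_mat), dimnames = dimnames(p_mat))
  structure(list(p = p_mat, n = n, snp = snp, groups = colnames(p_mat)),
            class = "freq_table")
}

# Slim admixture world for replicated qpAdm runs: same structure as the
# default study world, fewer individuals.
qpadm_config <- function(n_snps = 50000, n_per = 4,
                         target_weights = c(anatolia = 0.48, zagros = 0.33,
                                            levant = 0.19)) {
  pops <- list(
    pop_spec("outgroup", drift = 0.5, n_samples = n_per),
    pop_spec("anatolia", drift = 0.06, n_samples = n_per),
    pop_spec("zagros", drift = 0.10, n_samples = n_per),
    pop_spec("levant", drift = 0.08, n_samples = n_per),
    pop_spec("anatolia_ref", drift = 0.04, parent = "anatolia", n_samples = n_per),
    pop_spec("zagros_ref", drift = 0.04, parent = "zagros", n_samples = n_per),
    pop_spec("levant_ref", drift = 0.04, parent = "levant", n_samples = n_per),
    pop_spec("target", admixture_of = target_weights, n_samples = n_per)
  )
  sites <- default_sites()
  dates <- default_dates()
  sim_config(n_snps = n_snps, missingness = 1, error_rate = 0,
             populations = pops, pedigrees = list(),
             identical_pairs = tibble::tibble(src = character(), copy = character()),
             sites = sites, dates = dates, buildings = NULL)
}

expected_degree_from_theta <- function(theta) {
  cut(theta, c(-Inf, 0.03125, 0.09375, 0.1875, 0.375, Inf),
      labels = c("unrelated", "third", "second", "first", "identical"))
}
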