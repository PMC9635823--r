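#' Population specification for the synthetic world
#'
#' Describes one population as either (i) drifted from the shared ancestral
#' frequency pool under a Balding-Nichols model with divergence parameter
#' `drift` (F), (ii) drifted from another already-defined population
#' (`parent`), giving nested side branches, or (iii) an exact
#' frequency-space mixture of already-defined populations
#' (`admixture_of`). Exact mixture is what makes admixture-weight recovery
#' a well-posed truth.
#'
#' @param name Population label.
#' @param drift Balding-Nichols F in `[0, 1)`; 0 means no drift.
#' @param n_samples Number of unrelated individuals to emit.
#' @param admixture_of Named numeric vector of source weights (sum to 1).
#' @param parent Optional name of the population whose frequencies are the
#'   starting point for drift (default: the ancestral pool).
#' @return A `pop_spec` list.
#' @export
pop_spec <- function(name, drift = 0, n_samples = 0, admixture_of = NULL,
                     parent = NULL) {
  if (drift < 0 || drift >= 1) stop_pk("drift must be in [0, 1)")
  if (n_samples < 0) stop_pk("n_samples must be >= 0")
  if (!is.null(admixture_of)) {
    w <- admixture_of
    if (any(w <= 0) || abs(sum(w) - 1) > 1e-9) {
      stop_pk("admixture weights must be positive and sum to 1")
    }
    if (is.null(names(w)) || any(!nzchar(names(w)))) {
      stop_pk("admixture_of must be a named vector of source weights")
    }
  }
  structure(list(name = name, drift = drift, n_samples = n_samples,
                 admixture_of = admixture_of, parent = parent),
            class = "pop_spec")
}

#' Derive per-SNP allele frequencies for one population
#'
#' Unadmixed populations draw each SNP frequency from the Balding-Nichols
#' distribution `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the base frequency
#' `p` (the ancestral pool, or the parent population for side branches);
#' the mean is `p`, the variance `F p (1-p)`, so drift is unbiased.
#' Admixed populations are the exact mixture `sum_i w_i p_i` of
#' already-derived sources. Frequencies are clamped to
#' `[1e-6, 1 - 1e-6]` so no SNP is ever fully fixed.
#'
#' @param p_anc Ancestral frequency vector (all in (0, 1)).
#' @param spec A [pop_spec()].
#' @param derived Named list of frequency vectors for already-derived
#'   populations (sources / parents).
#' @param seed Optional integer seed.
#' @return Frequency vector of the same length as `p_anc`.
#' @export
derive_population_freqs <- function(p_anc, spec, derived = list(), seed = NULL) {
  if (any(p_anc <= 0 | p_anc >= 1)) stop_pk("ancestral freqs must be in (0, 1)")
  clamp <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  if (!is.null(spec$admixture_of)) {
    srcs <- names(spec$admixture_of)
    missing_src <- setdiff(srcs, names(derived))
    if (length(missing_src) > 0) {
      stop_pk("admixture source not yet derived: ", paste(missing_src, collapse = ", "))
    }
    p <- Reduce(`+`, Map(function(s, w) w * derived[[s]], srcs, spec$admixture_of))
    return(clamp(p))
  }
  base <- if (is.null(spec$parent)) p_anc else {
    if (is.null(derived[[spec$parent]])) stop_pk("parent not yet derived: ", spec$parent)
    derived[[spec$parent]]
  }
  f <- spec$drift
  if (f == 0) return(base)
  with_seed(seed, {
    p <- rbeta(length(base), base * (1 - f) / f, (1 - base) * (1 - f) / f)
    clamp(p)
  })
}

#' Drop genes through a pedigree
#'
#' Forward Mendelian transmission of founder genotypes drawn under
#' Hardy-Weinberg from the founder population's frequencies. Autosomal SNPs:
#' each parent passes one of its two alleles uniformly at random per SNP
#' (SNPs are transmitted independently; there is no linkage map). X SNPs:
#' mothers pass one of their two X alleles, fathers pass their single X to
#' daughters only; sons receive no paternal X and are hemizygous (calls
#' encoded 0/2).
#'
#' @param ped A [pedigree()].
#' @param founder_freqs Per-SNP allele1 frequencies of the founder
#'   population.
#' @param snp SNP table (autosomes and/or X).
#' @param seed Optional integer seed.
#' @return A diploid [geno_matrix()] over all pedigree members.
#' @export
gene_drop_pedigree <- function(ped, founder_freqs, snp, seed = NULL) {
  stopifnot(inherits(ped, "pk_pedigree"))
  n_snp <- nrow(snp)
  stopifnot(length(founder_freqs) == n_snp)
  on_x <- is_x_chrom(snp$chrom)
  ia <- which(!on_x); ix <- which(on_x)
  pa <- founder_freqs[ia]; px <- founder_freqs[ix]
  n <- nrow(ped)
  with_seed(seed, {
    H1a <- H2a <- matrix(0L, length(ia), n)   # paternal / maternal autosomal haplotypes
    X1 <- X2 <- matrix(0L, length(ix), n)     # females: two X; males: X1 only
    for (i in order(ped$depth)) {
      fa <- match(ped$father[i], ped$id)
      if (is.na(fa)) {
        H1a[, i] <- rbinom(length(ia), 1, pa)
        H2a[, i] <- rbinom(length(ia), 1, pa)
        X1[, i] <- rbinom(length(ix), 1, px)
        if (ped$sex[i] == "F") X2[, i] <- rbinom(length(ix), 1, px)
      } else {
        mo <- match(ped$mother[i], ped$id)
        pickf <- rbinom(length(ia), 1, 0.5) == 1L
        pickm <- rbinom(length(ia), 1, 0.5) == 1L
        H1a[, i] <- ifelse(pickf, H1a[, fa], H2a[, fa])
        H2a[, i] <- ifelse(pickm, H1a[, mo], H2a[, mo])
        xm <- ifelse(rbinom(length(ix), 1, 0.5) == 1L, X1[, mo], X2[, mo])
        if (ped$sex[i] == "M") {
          X1[, i] <- xm
        } else {
          X1[, i] <- X1[, fa]
          X2[, i] <- xm
        }
      }
    }
    calls <- matrix(NA_integer_, n_snp, n)
    calls[ia, ] <- H1a + H2a
    males <- ped$sex == "M"
    xc <- X1 + X2
    xc[, males] <- 2L * X1[, males, drop = FALSE]
    calls[ix, ] <- xc
    geno_matrix(calls, snp,
                tibble(id = ped$id, sex = ped$sex, population = "pedigree",
                       pseudo_haploid = FALSE))
  })
}

# Unrelated Hardy-Weinberg samples from a population's frequencies; males
# hemizygous on X.
sample_population <- function(freqs, snp, ids, sexes, population) {
  n_snp <- nrow(snp)
  on_x <- is_x_chrom(snp$chrom)
  k <- length(ids)
  calls <- matrix(0L, n_snp, k)
  na <- sum(!on_x); nx <- sum(on_x)
  calls[!on_x, ] <- rbinom(na * k, 2, freqs[!on_x])  # prob recycles per column
  if (nx > 0) {
    xf <- matrix(rbinom(nx * k, 2, freqs[on_x]), nx, k)
    xm <- matrix(2L * rbinom(nx * k, 1, freqs[on_x]), nx, k)
    male <- sexes == "M"
    xf[, male] <- xm[, male]
    calls[on_x, ] <- xf
  }
  geno_matrix(calls, snp, tibble(id = ids, sex = sexes, population = population,
                                 pseudo_haploid = FALSE))
}

#' Pseudo-haploidize a diploid genotype matrix
#'
#' Emulates random-haploid calling of low-coverage data: at every retained
#' site one allele is chosen uniformly from the individual's alleles,
#' flipped with probability `error_rate` (a symmetric allele flip; no
#' damage profile is modelled), and encoded as a homozygous 0/2 call. Each
#' site is independently retained with probability `missingness` (the
#' per-individual callable fraction).
#'
#' @param g A diploid (or hemizygous) [geno_matrix()].
#' @param missingness Callable fraction in `(0, 1]`; scalar or one value
#'   per individual. 0 produces an all-missing individual (legal, flagged).
#' @param error_rate Per-call flip probability in `[0, 0.5)`.
#' @param seed Optional integer seed.
#' @return A pseudo-haploid `geno_matrix`.
#' @export
pseudo_haploidize <- function(g, missingness = 1, error_rate = 0, seed = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (error_rate < 0 || error_rate >= 0.5) stop_pk("error_rate must be in [0, 0.5)")
  if (any(missingness < 0 | missingness > 1)) stop_pk("missingness must be in [0, 1]")
  n_ind <- nrow(g$ind)
  n_snp <- nrow(g$snp)
  miss <- rep_len(missingness, n_ind)
  with_seed(seed, {
    allele <- g$calls / 2
    het <- which(g$calls == 1L)
    allele[het] <- rbinom(length(het), 1, 0.5)
    if (error_rate > 0) {
      flip <- matrix(rbinom(n_snp * n_ind, 1, error_rate), n_snp, n_ind)
      allele <- abs(allele - flip)
    }
    keep <- matrix(runif(n_snp * n_ind), n_snp, n_ind) <=
      matrix(miss, n_snp, n_ind, byrow = TRUE)
    calls <- 2L * allele
    calls[!keep] <- NA_integer_
    out <- g
    out$calls <- calls
    out$ind$pseudo_haploid <- TRUE
    out <- geno_matrix(out$calls, out$snp, out$ind)
    empty <- colSums(!is.na(calls)) == 0
    if (any(empty)) {
      inform(paste0("all-missing individual(s) after pseudo-haploidization: ",
                    paste(out$ind$id[empty], collapse = ", ")))
    }
    out
  })
}

#' Human-like chromosome lengths for the simulator
#'
#' Twenty-two autosomes plus X with approximately human physical lengths;
#' SNP positions are drawn uniformly within these spans, which is what the
#' 1-Mb kinship windows and 5-Mb jackknife blocks tile.
#' @return Tibble with `name` and `length` (bp).
#' @export
default_chromosomes <- function() {
  tibble(
    name = c(as.character(1:22), "X"),
    length = c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 133,
               115, 107, 102, 90, 81, 78, 59, 63, 48, 51, 155) * 1e6
  )
}

default_populations <- function() {
  list(
    pop_spec("outgroup", drift = 0.5, n_samples = 6),
    pop_spec("anatolia", drift = 0.06, n_samples = 8),
    pop_spec("zagros", drift = 0.10, n_samples = 8),
    pop_spec("levant", drift = 0.08, n_samples = 8),
    pop_spec("anatolia_ref", drift = 0.04, parent = "anatolia", n_samples = 6),
    pop_spec("zagros_ref", drift = 0.04, parent = "zagros", n_samples = 6),
    pop_spec("levant_ref", drift = 0.04, parent = "levant", n_samples = 6),
    pop_spec("target",
             admixture_of = c(anatolia = 0.48, zagros = 0.33, levant = 0.19),
             n_samples = 6)
  )
}

# One extended family in the target population covering the planted
# relationship classes: parent-offspring, full siblings, grandmother,
# avuncular, paternal great-aunt (the discordant X configuration) and first
# cousins; plus a separate family providing the identical (twin) pair.
default_pedigrees <- function() {
  fam1 <- pedigree(tibble(
    id = c("ggf", "ggm", "gmA", "gaunt", "gfA", "fa1", "mo1",
           "uncle", "usp", "child1", "child2", "cousin"),
    sex = c("M", "F", "F", "F", "M", "M", "F", "M", "F", "F", "M", "F"),
    father = c(NA, NA, "ggf", "ggf", NA, "gfA", NA, "gfA", NA, "fa1", "fa1", "uncle"),
    mother = c(NA, NA, "ggm", "ggm", NA, "gmA", NA, "gmA", NA, "mo1", "mo1", "usp")
  ))
  fam2 <- pedigree(tibble(
    id = c("fa2", "mo2", "tw1"),
    sex = c("M", "F", "F"),
    father = c(NA, NA, "fa2"),
    mother = c(NA, NA, "mo2")
  ))
  list(
    list(ped = fam1, population = "target",
         emit = c("gmA", "gaunt", "fa1", "mo1", "uncle", "child1", "child2", "cousin")),
    list(ped = fam2, population = "target", emit = c("tw1"))
  )
}

default_sites <- function() {
  tibble(
    population = c("outgroup", "anatolia", "zagros", "levant",
                   "anatolia_ref", "zagros_ref", "levant_ref", "target"),
    site = c("OUT", "ANA", "ZAG", "LEV", "ANA2", "ZAG2", "LEV2", "TEPE"),
    lat = c(7.4, 37.6, 34.2, 31.5, 38.4, 35.3, 30.8, 38.2),
    lon = c(3.9, 32.5, 47.1, 35.4, 33.9, 46.4, 34.8, 39.7)
  )
}

default_dates <- function() {
  tibble(
    population = c("outgroup", "anatolia", "zagros", "levant",
                   "anatolia_ref", "zagros_ref", "levant_ref", "target"),
    date_mean = c(0, 8800, 8600, 8900, 8500, 8300, 8600, 8300),
    date_sd = c(10, 150, 150, 150, 150, 150, 150, 120)
  )
}

# Coburial plan for the target site, mirroring a small number of domestic
# buildings holding close kin, extended kin and unrelated individuals.
default_buildings <- function() {
  tibble(
    id = c("fa1", "child2", "tw1", "tw1_dup", "target_1",
           "uncle", "gmA", "mo1", "target_2",
           "child1", "gaunt", "cousin", "target_3"),
    building = rep(c("CA", "CL", "CN"), c(5, 4, 4))
  )
}

#' Simulation configuration
#'
#' Bundles every dial of the synthetic world. The defaults are the study
#' conditions used throughout the package's validation: an outgroup plus a
#' three-source east-west structure with a 0.48/0.33/0.19 admixed target,
#' drifted side branches serving as the qpAdm reference set, planted
#' pedigrees including an identical pair and a paternal great-aunt
#' configuration, 70% per-site callability and a 0.5% allele-flip error.
#'
#' @param n_snps Total SNPs (allocated to chromosomes by length).
#' @param chromosomes Tibble of chromosome `name`, `length` (bp).
#' @param ancestral_freq_range Bounds of the uniform ancestral frequency
#'   draw; the default (0.05, 0.95) keeps every SNP polymorphic, mirroring a
#'   common-variant (MAF > 10%) panel philosophy.
#' @param missingness Per-individual callable fraction in (0, 1].
#' @param error_rate Per-call flip probability in `[0, 0.5)`.
#' @param populations List of [pop_spec()]s.
#' @param pedigrees List of `list(ped =, population =, emit =)` entries.
#' @param identical_pairs Tibble with `src` ids to duplicate and the new
#'   `copy` ids (identical underlying diploid genomes, independently
#'   pseudo-haploidized).
#' @param sites,dates,buildings Metadata plans (per-population site
#'   coordinates, date mean/sd in cal BCE, per-individual building labels).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 20000,
                       chromosomes = default_chromosomes(),
                       ancestral_freq_range = c(0.05, 0.95),
                       missingness = 0.7,
                       error_rate = 0.005,
                       populations = default_populations(),
                       pedigrees = default_pedigrees(),
                       identical_pairs = tibble(src = "tw1", copy = "tw1_dup"),
                       sites = default_sites(),
                       dates = default_dates(),
                       buildings = default_buildings()) {
  lo <- ancestral_freq_range[1]; hi <- ancestral_freq_range[2]
  if (!(0 < lo && lo < hi && hi < 1)) stop_pk("ancestral_freq_range must satisfy 0 < low < high < 1")
  if (error_rate < 0 || error_rate >= 0.5) stop_pk("error_rate must be in [0, 0.5)")
  structure(list(n_snps = n_snps, chromosomes = as_tibble(chromosomes),
                 ancestral_freq_range = ancestral_freq_range,
                 missingness = missingness, error_rate = error_rate,
                 populations = populations, pedigrees = pedigrees,
                 identical_pairs = identical_pairs,
                 sites = as_tibble(sites), dates = as_tibble(dates),
                 buildings = buildings),
            class = "sim_config")
}

# Build the SNP table: counts per chromosome proportional to length,
# positions uniform and strictly increasing, alleles drawn from ACGT.
sim_snp_table <- function(config) {
  chr <- config$chromosomes
  n <- config$n_snps
  counts <- floor(n * chr$length / sum(chr$length))
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(n * chr$length / sum(chr$length) - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  snp <- purrr::map2_dfr(seq_len(nrow(chr)), counts, function(i, k) {
    if (k == 0) return(NULL)
    pos <- sort(sample.int(chr$length[i], k))
    tibble(chrom = chr$name[i], physical_pos = pos)
  })
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, nrow(snp), replace = TRUE)
  shift <- sample.int(3, nrow(snp), replace = TRUE)
  a2 <- bases[(match(a1, bases) - 1 + shift) %% 4 + 1]
  snp %>%
    mutate(snp_id = paste0("rs", dplyr::row_number()),
           genetic_pos = 0, allele1 = a1, allele2 = a2) %>%
    select("snp_id", "chrom", "genetic_pos", "physical_pos", "allele1", "allele2")
}

resolve_ancestry <- function(populations) {
  specs <- setNames(populations, vapply(populations, `[[`, "", "name"))
  anc <- list()
  resolve <- function(nm) {
    if (!is.null(anc[[nm]])) return(anc[[nm]])
    sp <- specs[[nm]]
    w <- if (!is.null(sp$admixture_of)) {
      ws <- lapply(names(sp$admixture_of), resolve)
      out <- list()
      for (k in seq_along(ws)) {
        for (src in names(ws[[k]])) {
          out[[src]] <- (out[[src]] %||% 0) + sp$admixture_of[k] * ws[[k]][[src]]
        }
      }
      out
    } else if (!is.null(sp$parent)) {
      resolve(sp$parent)
    } else {
      setNames(list(1), nm)
    }
    anc[[nm]] <<- w
    w
  }
  lapply(names(specs), resolve) %>% setNames(names(specs))
}

#' Simulate a complete synthetic dataset
#'
#' Generates the full synthetic study: ancestral frequencies, per-population
#' drifted/admixed frequencies, unrelated Hardy-Weinberg samples, planted
#' pedigrees by gene dropping, identical-pair duplication, pseudo-haploid
#' observation with missingness and error, sample metadata (site, building,
#' coordinates, dates) and a truth table with every individual's ancestry
#' weights and every planted pair's expected autosomal and X kinship.
#' A fixed seed reproduces every artifact exactly.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (required: the whole dataset is a deterministic
#'   function of it).
#' @return A `pk_sim` list: `geno` (pseudo-haploid), `diploid`, `meta`,
#'   `truth` (list of `ancestry` and `relations` tibbles), `freqs` (true
#'   per-population frequency matrix), `ages` (named list of
#'   [age_distribution()]s), `config`, `seed`.
#' @export
simulate_dataset <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  snp <- with_seed(child_seed(seed, 1), sim_snp_table(config))
  rng <- config$ancestral_freq_range
  p_anc <- with_seed(child_seed(seed, 2),
                     runif(nrow(snp), rng[1], rng[2]))

  specs <- config$populations
  names(specs) <- vapply(specs, `[[`, "", "name")
  derived <- list()
  pending <- names(specs)
  k <- 0
  while (length(pending) > 0) {
    k <- k + 1
    if (k > length(specs)^2 + 1) stop_pk("circular population dependencies")
    nm <- pending[1]
    sp <- specs[[nm]]
    deps <- c(names(sp$admixture_of), sp$parent)
    if (all(deps %in% names(derived))) {
      derived[[nm]] <- derive_population_freqs(p_anc, sp, derived,
                                               seed = child_seed(seed, 10 + k))
      pending <- pending[-1]
    } else {
      pending <- c(pending[-1], nm)
    }
  }

  # unrelated samples
  genos <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (sp$n_samples == 0) next
    ids <- paste0(sp$name, "_", seq_len(sp$n_samples))
    sexes <- rep(c("F", "M"), length.out = sp$n_samples)
    genos[[length(genos) + 1]] <- with_seed(
      child_seed(seed, 100 + i),
      sample_population(derived[[sp$name]], snp, ids, sexes, sp$name)
    )
  }

  # pedigrees
  relations <- list()
  for (i in seq_along(config$pedigrees)) {
    pd <- config$pedigrees[[i]]
    g <- gene_drop_pedigree(pd$ped, derived[[pd$population]], snp,
                            seed = child_seed(seed, 200 + i))
    g$ind$population <- pd$population
    emit <- pd$emit %||% pd$ped$id
    g <- subset_geno(g, inds = emit)
    genos[[length(genos) + 1]] <- g
    if (length(emit) > 1) {
      prs <- utils::combn(emit, 2)
      relations[[length(relations) + 1]] <- tibble(
        id1 = prs[1, ], id2 = prs[2, ],
        theta_auto = purrr::map2_dbl(prs[1, ], prs[2, ],
                                     ~kinship_auto(pd$ped, .x, .y)),
        theta_x = purrr::map2_dbl(prs[1, ], prs[2, ],
                                  ~kinship_x(pd$ped, .x, .y))
      )
    }
  }

  calls <- do.call(cbind, lapply(genos, function(g) g$calls))
  ind <- bind_rows(lapply(genos, function(g) g$ind))
  if (anyDuplicated(ind$id)) stop_pk("duplicate individual ids in simulation")

  # identical pairs: duplicate the diploid genome under a new id
  ip <- config$identical_pairs
  if (!is.null(ip) && nrow(ip) > 0) {
    for (r in seq_len(nrow(ip))) {
      j <- match(ip$src[r], ind$id)
      if (is.na(j)) stop_pk("identical-pair source not emitted: ", ip$src[r])
      calls <- cbind(calls, calls[, j])
      ind <- bind_rows(ind, mutate(ind[j, ], id = ip$copy[r]))
      relations[[length(relations) + 1]] <- tibble(
        id1 = ip$src[r], id2 = ip$copy[r], theta_auto = 0.5,
        theta_x = if (ind$sex[j] == "F") 0.5 else 1.0
      )
    }
  }
  diploid <- geno_matrix(calls, snp, ind)

  geno <- pseudo_haploidize(diploid, missingness = config$missingness,
                            error_rate = config$error_rate,
                            seed = child_seed(seed, 300))

  # metadata
  pops <- ind$population
  meta <- tibble(id = ind$id, population = pops, sex = ind$sex) %>%
    left_join(config$sites, by = "population") %>%
    left_join(config$dates, by = "population")
  if (!is.null(config$buildings)) {
    meta <- left_join(meta, config$buildings, by = "id")
  } else meta$building <- NA_character_
  meta$date_mean <- meta$date_mean +
    with_seed(child_seed(seed, 400), round(stats::rnorm(nrow(meta), 0, 80)))
  meta <- meta[, c("id", "population", "site", "building", "sex", "lat", "lon",
                   "date_mean", "date_sd")]

  ages <- setNames(
    lapply(seq_len(nrow(meta)), function(i) {
      age_grid_gaussian(meta$date_mean[i], meta$date_sd[i])
    }),
    meta$id
  )

  anc_w <- resolve_ancestry(config$populations)
  base_pops <- sort(unique(unlist(lapply(anc_w, names))))
  ancestry <- purrr::map_dfr(seq_len(nrow(ind)), function(i) {
    w <- anc_w[[ind$population[i]]]
    row <- setNames(as.list(rep(0, length(base_pops))), base_pops)
    for (nm in names(w)) row[[nm]] <- w[[nm]]
    as_tibble(c(list(id = ind$id[i]), row))
  })

  structure(list(
    geno = geno, diploid = diploid, meta = meta,
    truth = list(ancestry = ancestry,
                 relations = if (length(relations)) bind_rows(relations) else tibble()),
    freqs = do.call(cbind, derived), snp = snp, ages = ages,
    config = config, seed = seed
  ), class = "pk_sim")
}

#' @export
print.pk_sim <- function(x, ...) {
  cat("<pk_sim> seed ", x$seed, ": ", nrow(x$snp), " SNPs, ",
      nrow(x$meta), " individuals, ",
      nrow(x$truth$relations), " planted related pairs\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the EIGENSTRAT trio (`sim.geno`/`.snp`/`.ind`), the sample
#' metadata as tab-separated text, the truth table as JSON and one
#' two-column age grid per individual. Output is byte-identical for a
#' fixed simulation seed.
#'
#' @param sim A `pk_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "pk_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_eigenstrat(sim$geno, file.path(dir, "sim"))
  meta <- sim$meta
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(ancestry = sim$truth$ancestry, relations = sim$truth$relations,
                seed = sim$seed)
  writeLines(jsonlite::toJSON(truth, digits = NA, pretty = TRUE),
             file.path(dir, "truth.json"))
  dd <- file.path(dir, "dates")
  dir.create(dd, showWarnings = FALSE)
  for (id in names(sim$ages)) {
    a <- sim$ages[[id]]
    utils::write.table(tibble(year_calBCE = a$year, mass = a$mass),
                       file.path(dd, paste0(id, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Serial-founder cline configuration for isolation-by-distance checks
#'
#' A chain of populations along a longitudinal transect, each drifted from
#' its western neighbour by `step_drift`, so pairwise genetic divergence
#' grows with geographic separation. Optionally one population receives
#' extra private drift, emulating a strongly differentiated group that
#' should surface in the regression residuals.
#'
#' @param n_pops Number of populations along the cline.
#' @param n_per_pop Individuals per population.
#' @param step_drift Balding-Nichols F added between neighbours.
#' @param extra_drift_pop Index of the population given extra drift (or
#'   `NULL`).
#' @param extra_drift Additional F for that population.
#' @param n_snps Total SNPs.
#' @return A [sim_config()].
#' @export
sim_cline_config <- function(n_pops = 8, n_per_pop = 4, step_drift = 0.02,
                             extra_drift_pop = NULL, extra_drift = 0.1,
                             n_snps = 12000) {
  # Serial-founder chain of unsampled nodes with one sampled population per
  # node. Outgroup f3 between two individuals measures their shared drift
  # path, so drift private to one terminal branch cannot move cross-site
  # dissimilarities; a "more differentiated" population is therefore
  # emulated as an earlier-diverging long branch (it attaches two nodes
  # upstream with extra branch drift), which shortens its shared path with
  # every neighbour and is exactly what the (1 - f3) residuals respond to.
  pops <- list(pop_spec("outgroup", drift = 0.5, n_samples = 4))
  for (i in seq_len(n_pops)) {
    pops[[length(pops) + 1]] <- pop_spec(
      paste0("node", i), drift = step_drift,
      parent = if (i == 1) NULL else paste0("node", i - 1), n_samples = 0)
    deep <- !is.null(extra_drift_pop) && i == extra_drift_pop
    pops[[length(pops) + 1]] <- pop_spec(
      paste0("pop", i),
      drift = if (deep) extra_drift else 0,
      parent = paste0("node", if (deep) max(1, i - 3) else i),
      n_samples = n_per_pop)
  }
  sites <- tibble(
    population = c("outgroup", paste0("pop", seq_len(n_pops))),
    site = c("OUT", paste0("S", seq_len(n_pops))),
    lat = c(7.4, rep(36.5, n_pops)),
    lon = c(3.9, 30 + 2.5 * seq_len(n_pops))
  )
  dates <- tibble(
    population = sites$population,
    date_mean = c(0, rep(8500, n_pops)),
    date_sd = c(10, rep(120, n_pops))
  )
  sim_config(n_snps = n_snps, populations = pops, pedigrees = list(),
             identical_pairs = tibble(src = character(), copy = character()),
             sites = sites, dates = dates, buildings = NULL)
}
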