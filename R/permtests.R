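# Permutation tests over individuals' group labels. The permutation unit is
# the individual, not the pair: pairs sharing an individual are dependent,
# and shuffling individual labels preserves that dependence structure under
# the null.

# Named symmetric lookup of pair genetic distances.
pair_dist_matrix <- function(pairs, ids = NULL) {
  ids <- ids %||% sort(unique(c(pairs$id1, pairs$id2)))
  pairs <- pairs[pairs$id1 %in% ids & pairs$id2 %in% ids, ]
  D <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(pairs$id1, ids); j <- match(pairs$id2, ids)
  D[cbind(i, j)] <- pairs$dist_gen
  D[cbind(j, i)] <- pairs$dist_gen
  D
}

perm_result <- function(statistic, effect_size, n_perm, p, sided, seed) {
  tibble(statistic = statistic, effect_size = effect_size, n_perm = n_perm,
         p = p, sided = sided, seed = seed %||% NA_integer_)
}

#' Within-site diversity contrast by permutation
#'
#' Compares the median within-site pair dissimilarity (1 - f3) between
#' sites — a low median marks a genetically homogeneous (low-diversity)
#' group. For every site pair the observed difference of medians is tested
#' against a null built by shuffling individuals' site labels (preserving
#' site sizes) and recomputing the within-site medians; two-sided p with
#' add-one correction.
#'
#' @param pairs Pair table (all pairs, unfiltered) with `dist_gen`.
#' @param sites Named character vector mapping individual id -> site.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param min_n Minimum individuals per site (smaller sites are excluded
#'   with a log message).
#' @return Tibble: one row per site contrast with medians, effect size
#'   (difference of medians), and permutation p; per-site medians in
#'   attribute `site_medians`.
#' @export
diversity_permutation <- function(pairs, sites, n_perm = 1000, seed = NULL,
                                  min_n = 2) {
  ids <- intersect(names(sites), unique(c(pairs$id1, pairs$id2)))
  sites <- sites[ids]
  tab <- table(sites)
  small <- names(tab)[tab < min_n]
  if (length(small) > 0) {
    inform(paste0("sites excluded (<", min_n, " individuals): ",
                  paste(small, collapse = ", ")))
    ids <- ids[!sites[ids] %in% small]
    sites <- sites[ids]
  }
  use_sites <- sort(unique(unname(sites)))
  if (length(use_sites) < 2) stop_pk("need at least 2 sites with enough individuals")
  D <- pair_dist_matrix(pairs, ids)
  lab <- unname(sites[ids])
  within_medians <- function(lab) {
    vapply(use_sites, function(s) {
      sub <- D[lab == s, lab == s, drop = FALSE]
      median(sub[upper.tri(sub)], na.rm = TRUE)
    }, numeric(1))
  }
  obs <- within_medians(lab)
  cons <- utils::combn(use_sites, 2)
  obs_diff <- obs[cons[1, ]] - obs[cons[2, ]]
  with_seed(seed, {
    exceed <- numeric(ncol(cons))
    for (b in seq_len(n_perm)) {
      md <- within_medians(sample(lab))
      nd <- md[cons[1, ]] - md[cons[2, ]]
      exceed <- exceed + (abs(nd) >= abs(obs_diff) - 1e-15)
    }
    out <- tibble(
      site1 = cons[1, ], site2 = cons[2, ],
      median1 = unname(obs[cons[1, ]]), median2 = unname(obs[cons[2, ]]),
      effect_size = unname(obs_diff),
      n_perm = n_perm,
      p = unname(exceed + 1) / (n_perm + 1),
      sided = "two-sided", seed = seed %||% NA_integer_
    )
    attr(out, "site_medians") <- tibble(site = use_sites, median = unname(obs))
    out
  })
}

#' Coburial permutation test
#'
#' Tests whether individuals buried in the same building are genetically
#' closer to each other than to individuals from other buildings, after
#' excluding close genetic kin. The observed effect size is
#' `mean(1 - f3, between-building pairs) - mean(1 - f3, within-building
#' pairs)` (positive = coburied pairs are closer); the null permutes
#' individuals' building assignments, preserving building sizes, and the
#' one-sided p-value carries the add-one correction.
#'
#' @param pairs Pair table with `dist_gen` and `close_kin`.
#' @param buildings Named character vector id -> building; individuals
#'   without a building are excluded.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @return One-row tibble: observed statistic (mean within-building
#'   dissimilarity), `effect_size`, `n_perm`, `p`, `sided`, `seed`.
#' @export
coburial_permutation <- function(pairs, buildings, n_perm = 1000, seed = NULL) {
  buildings <- buildings[!is.na(buildings)]
  ids <- intersect(names(buildings), unique(c(pairs$id1, pairs$id2)))
  if (length(unique(buildings[ids])) < 2) {
    stop_pk("need at least 2 buildings with analysed individuals")
  }
  D <- pair_dist_matrix(pairs, ids)
  kin_excl <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  kk <- pairs[pairs$close_kin & pairs$id1 %in% ids & pairs$id2 %in% ids, ]
  if (nrow(kk) > 0) {
    kin_excl[cbind(match(kk$id1, ids), match(kk$id2, ids))] <- TRUE
    kin_excl[cbind(match(kk$id2, ids), match(kk$id1, ids))] <- TRUE
  }
  lab <- unname(buildings[ids])
  ut <- upper.tri(D)
  usable <- ut & !kin_excl & !is.na(D)
  effect <- function(lab) {
    same <- outer(lab, lab, `==`)
    w <- usable & same
    b <- usable & !same
    if (!any(w) || !any(b)) return(NA_real_)
    mean(D[b]) - mean(D[w])
  }
  obs <- effect(lab)
  if (is.na(obs)) stop_pk("degenerate grouping: no usable within- or between-building pair")
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(b) effect(sample(lab)), numeric(1))
    p <- (sum(null >= obs - 1e-15, na.rm = TRUE) + 1) / (sum(!is.na(null)) + 1)
    out <- perm_result(statistic = obs, effect_size = obs, n_perm = n_perm,
                       p = p, sided = "one-sided (within closer)", seed = seed)
    attr(out, "null") <- null
    out
  })
}
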