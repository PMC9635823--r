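# Per-window mismatch/overlap arrays for a set of pseudo-haploid
# individuals. Windows are half-open [start, start + window_bp) physical
# intervals from position 1. Returns window index tibble plus 3D arrays
# mism[w, i, j], over[w, i, j].
pair_window_arrays <- function(g, ids, window_bp = 1e6) {
  gg <- subset_geno(g, inds = ids)
  if (any(!gg$ind$pseudo_haploid)) {
    stop_pk("kinship mismatch rates require pseudo-haploid individuals; ",
            "pseudo-haploidize first: ",
            paste(gg$ind$id[!gg$ind$pseudo_haploid], collapse = ", "))
  }
  H <- gg$calls / 2
  V <- !is.na(H)
  H0 <- H; H0[!V] <- 0
  win_raw <- paste0(gg$snp$chrom, ":", (gg$snp$physical_pos - 1) %/% window_bp)
  wid <- match(win_raw, unique(win_raw))
  nw <- max(wid)
  n <- length(ids)
  mism <- array(0, c(nw, n, n))
  over <- array(0, c(nw, n, n))
  idx_by_w <- split(seq_len(nrow(gg$snp)), wid)
  for (w in seq_len(nw)) {
    rows <- idx_by_w[[w]]
    Aw <- H0[rows, , drop = FALSE]
    Vw <- V[rows, , drop = FALSE] * 1
    ca <- crossprod(Aw, Vw)
    mism[w, , ] <- ca + t(ca) - 2 * crossprod(Aw)
    over[w, , ] <- crossprod(Vw)
  }
  wtab <- tibble(window = seq_len(nw)) %>%
    mutate(chrom = sub(":.*", "", unique(win_raw)),
           start = as.numeric(sub(".*:", "", unique(win_raw))) * window_bp + 1)
  list(ids = ids, windows = wtab, mism = mism, over = over)
}

#' Windowed pairwise mismatch rates (P0) for one pair
#'
#' The READ-style primitive: within each 1-Mb physical window, the fraction
#' of jointly called pseudo-haploid sites at which the two haploid calls
#' differ. Empty windows are omitted.
#'
#' @param g A [geno_matrix()] (pseudo-haploid individuals).
#' @param pair Character vector of two ids.
#' @param window_bp Window span in bp (default 1 Mb).
#' @return Tibble with `chrom`, `start`, `n_overlap`, `n_mismatch`, `p0`.
#' @export
windowed_p0 <- function(g, pair, window_bp = 1e6) {
  stopifnot(length(pair) == 2)
  pw <- pair_window_arrays(g, pair, window_bp)
  out <- pw$windows %>%
    mutate(n_overlap = as.integer(pw$over[, 1, 2]),
           n_mismatch = as.integer(round(pw$mism[, 1, 2])),
           p0 = .data$n_mismatch / .data$n_overlap) %>%
    filter(.data$n_overlap > 0) %>%
    select("chrom", "start", "n_overlap", "n_mismatch", "p0")
  out
}

#' Normalize genome-wide P0 values
#'
#' Divides each pair's genome-wide mismatch rate by a baseline representing
#' an unrelated pair: by default the median P0 over all pairs in the sample
#' (assuming most pairs are unrelated), or an explicit fixed baseline.
#' `theta = 1 - normalized P0` is then the kinship coefficient estimate.
#'
#' @param p0 Numeric vector of genome-wide P0 values (one per pair).
#' @param method `"median"` (default) or `"fixed"`.
#' @param baseline Baseline P0 for `method = "fixed"`.
#' @return List with `baseline` and `normalized`.
#' @export
normalize_p0 <- function(p0, method = c("median", "fixed"), baseline = NULL) {
  method <- match.arg(method)
  if (method == "median") {
    ok <- !is.na(p0)
    if (sum(ok) < 3) stop_pk("median baseline needs at least 3 pairs")
    baseline <- median(p0[ok])
  } else if (is.null(baseline)) stop_pk("fixed method needs a baseline")
  if (!is.finite(baseline) || baseline == 0) stop_pk("baseline P0 must be non-zero")
  list(baseline = baseline, normalized = p0 / baseline)
}

#' Classify relatedness degree from normalized P0
#'
#' Expected normalized P0 is 0.5, 0.75, 0.875, 0.9375 and 1 for
#' identical/twin, first-, second-, third-degree and unrelated pairs;
#' assignment uses the midpoint cutoffs 0.625, 0.8125, 0.90625, 0.96875.
#' A pair is demoted to unrelated when its deviation from 1 is not
#' significant (`|1 - normalized| / se <= z_min`, default 2), and flagged
#' `insufficient-data` when its overlapping-SNP count does not exceed
#' `min_snps` (2000 for autosomes, 200 for the X).
#'
#' @param normalized Normalized P0 values.
#' @param se Standard errors of normalized P0 (window-based).
#' @param n_snps Overlapping SNP counts.
#' @param min_snps Required overlap; a pair needs `n_snps > min_snps`.
#' @param z_min Significance threshold on `|Z|` vs the unrelated
#'   expectation.
#' @param cutoffs Midpoint bin edges.
#' @return Tibble with `degree` and `z_unrelated`.
#' @export
classify_degree <- function(normalized, se, n_snps,
                            min_snps = 2000, z_min = 2,
                            cutoffs = c(0.625, 0.8125, 0.90625, 0.96875)) {
  bins <- c("identical", "first", "second", "third", "unrelated")
  bin <- bins[findInterval(normalized, cutoffs) + 1]
  z <- (1 - normalized) / se
  i0 <- which(!is.na(se) & se == 0)
  z[i0] <- ifelse(normalized[i0] == 1, 0, Inf)
  demote <- bin != "unrelated" & is.finite(z) & abs(z) <= z_min
  bin[demote] <- "unrelated"
  bin[is.na(normalized)] <- "insufficient-data"
  bin[n_snps <= min_snps] <- "insufficient-data"
  tibble(degree = factor(bin, levels = c(bins, "insufficient-data")),
         z_unrelated = z)
}

#' READ-style pairwise kinship estimation
#'
#' The full pipeline for one chromosome class: per-pair mismatch rates in
#' 1-Mb windows, overlap-weighted genome-wide P0, normalization by the
#' sample median (an unrelated-pair baseline), `theta = 1 - normalized P0`,
#' a window-based standard error (overlap-weighted SD of window P0 divided
#' by the square root of the window count, scaled by the baseline), and
#' degree classification with the `|Z| > 2` significance rule and the
#' minimum-overlap thresholds (> 2000 autosomal SNPs, > 200 X SNPs).
#'
#' @param g A [geno_matrix()] containing pseudo-haploid individuals.
#' @param ids Individuals to analyse (default: all pseudo-haploid ones).
#' @param chrom_class `"autosomal"` or `"X"` (X excludes PAR-masked SNPs).
#' @param window_bp Window span (default 1 Mb).
#' @param min_snps Minimum overlap; defaults to 2000 (autosomal) or 200 (X).
#' @param z_min `|Z|` threshold for calling a pair related.
#' @param baseline Fixed baseline P0; `NULL` (default) uses the median over
#'   pairs.
#' @return A `pk_kinship` tibble, one row per unordered pair: `id1`, `id2`,
#'   `chrom_class`, `n_snps`, `n_windows`, `p0`, `baseline`, `normalized`,
#'   `theta`, `se`, `z_unrelated`, `degree`.
#' @export
kinship_read <- function(g, ids = NULL, chrom_class = c("autosomal", "X"),
                         window_bp = 1e6, min_snps = NULL, z_min = 2,
                         baseline = NULL) {
  chrom_class <- match.arg(chrom_class)
  min_snps <- min_snps %||% if (chrom_class == "autosomal") 2000 else 200
  gg <- chrom_class_geno(g, chrom_class)
  ids <- ids %||% gg$ind$id[gg$ind$pseudo_haploid]
  if (length(ids) < 2) stop_pk("need at least 2 individuals")
  pw <- pair_window_arrays(gg, ids, window_bp)
  n <- length(ids)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  stats <- purrr::map_dfr(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    ov <- pw$over[, i, j]; mm <- pw$mism[, i, j]
    use <- ov > 0
    n_tot <- sum(ov)
    if (n_tot == 0) {
      return(tibble(id1 = ids[i], id2 = ids[j], n_snps = 0L, n_windows = 0L,
                    p0 = NA_real_, se_p0 = NA_real_))
    }
    p0w <- mm[use] / ov[use]
    w <- ov[use]
    p0 <- sum(mm) / n_tot
    nw <- sum(use)
    se_p0 <- if (nw >= 2) {
      wsd <- sqrt(sum(w * (p0w - p0)^2) / sum(w) * nw / (nw - 1))
      wsd / sqrt(nw)
    } else NA_real_
    tibble(id1 = ids[i], id2 = ids[j], n_snps = as.integer(n_tot),
           n_windows = nw, p0 = p0, se_p0 = se_p0)
  })
  nrm <- if (is.null(baseline)) normalize_p0(stats$p0, "median")
         else normalize_p0(stats$p0, "fixed", baseline)
  stats$baseline <- nrm$baseline
  stats$normalized <- nrm$normalized
  stats$theta <- 1 - stats$normalized
  stats$se <- stats$se_p0 / nrm$baseline
  cls <- classify_degree(stats$normalized, stats$se, stats$n_snps,
                         min_snps = min_snps, z_min = z_min)
  stats$z_unrelated <- cls$z_unrelated
  stats$degree <- cls$degree
  out <- stats %>%
    mutate(chrom_class = chrom_class) %>%
    select("id1", "id2", "chrom_class", "n_snps", "n_windows", "p0",
           "baseline", "normalized", "theta", "se", "z_unrelated", "degree")
  class(out) <- c("pk_kinship", class(out))
  attr(out, "params") <- list(window_bp = window_bp, min_snps = min_snps,
                              z_min = z_min,
                              se_estimator = "overlap-weighted window SD / sqrt(n_windows), scaled by 1/baseline",
                              cutoffs = c(0.625, 0.8125, 0.90625, 0.96875))
  out
}

#' Kinship coefficient from the nine condensed Jaccard coefficients
#'
#' `theta = J1 + 0.5 (J3 + J5 + J7) + 0.25 J8`, the combination used by
#' genotype-likelihood kinship estimators.
#'
#' @param j Numeric vector of the nine coefficients J1..J9 (non-negative,
#'   summing to 1).
#' @return The kinship coefficient.
#' @export
theta_from_jaccard <- function(j) {
  if (length(j) != 9) stop_pk("expected 9 Jaccard coefficients")
  if (any(j < 0)) stop_pk("Jaccard coefficients must be non-negative")
  if (abs(sum(j) - 1) > 1e-9) stop_pk("Jaccard coefficients must sum to 1")
  unname(j[1] + 0.5 * (j[3] + j[5] + j[7]) + 0.25 * j[8])
}

#' Detect identical individuals and propose merges
#'
#' Collects pairs classified `identical` into connected groups (a chain
#' A=B, B=C merges all three, with a warning) and proposes one merged id
#' per group.
#'
#' @param estimates A `pk_kinship` tibble from [kinship_read()].
#' @return Tibble with `merged_id` and list-column `ids`.
#' @export
detect_identicals <- function(estimates) {
  hits <- estimates %>% filter(.data$degree == "identical")
  if (nrow(hits) == 0) {
    return(tibble(merged_id = character(), ids = list()))
  }
  ids <- unique(c(hits$id1, hits$id2))
  parent <- setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (r in seq_len(nrow(hits))) {
    a <- find(hits$id1[r]); b <- find(hits$id2[r])
    if (a != b) parent[[a]] <- b
  }
  roots <- vapply(ids, find, character(1))
  groups <- split(ids, roots)
  chained <- vapply(groups, length, 1L) > 2
  if (any(chained)) {
    warn(paste0("chained identity group(s) merged: ",
                paste(vapply(groups[chained], paste, "", collapse = "+"),
                      collapse = "; ")))
  }
  tibble(
    merged_id = vapply(groups, function(g) paste(sort(g), collapse = "+"), ""),
    ids = unname(lapply(groups, sort))
  )
}

#' Merge identical individuals' call vectors
#'
#' Unions the pseudo-haploid call vectors of each group: a site called in
#' only one member takes that call; conflicting co-called sites are set
#' missing (conservative, preserving pseudo-haploid semantics), and the
#' conflict rate is reported.
#'
#' @param g A [geno_matrix()].
#' @param merges Output of [detect_identicals()].
#' @return A `geno_matrix` with each group replaced by its merged
#'   individual; per-group conflict rates in attribute `merge_log`.
#' @export
merge_identicals <- function(g, merges) {
  if (nrow(merges) == 0) return(g)
  log <- list()
  for (r in seq_len(nrow(merges))) {
    ids <- merges$ids[[r]]
    cols <- g$calls[, ids, drop = FALSE]
    called <- !is.na(cols)
    n_called <- rowSums(called)
    mx <- suppressWarnings(apply(cols, 1, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) return(NA_integer_)
      if (length(unique(x)) > 1) return(-1L)  # conflict marker
      x[1]
    }))
    conflict <- mx == -1L & !is.na(mx)
    merged <- mx
    merged[conflict] <- NA_integer_
    co_called <- n_called >= 2
    rate <- if (any(co_called)) mean(conflict[co_called]) else 0
    log[[merges$merged_id[r]]] <- tibble(
      merged_id = merges$merged_id[r], n_co_called = sum(co_called),
      n_conflict = sum(conflict), conflict_rate = rate
    )
    j <- match(ids[1], g$ind$id)
    keep <- setdiff(g$ind$id, ids)
    new_ind <- bind_rows(g$ind[match(keep, g$ind$id), ],
                         mutate(g$ind[j, ], id = merges$merged_id[r]))
    g <- geno_matrix(cbind(g$calls[, keep, drop = FALSE], merged),
                     g$snp, new_ind)
    inform(sprintf("merged %s: %d co-called sites, conflict rate %.3f",
                   merges$merged_id[r], sum(co_called), rate))
  }
  attr(g, "merge_log") <- bind_rows(log)
  g
}

#' Compare autosomal and X kinship for a pair
#'
#' An X estimate exceeding the autosomal one beyond 2 combined SEs is the
#' signature of a paternal-side relationship for female pairs (the X passes
#' through the father untouched); a deficit points to configurations with a
#' male-male link. When the combined uncertainty cannot resolve one degree
#' step (2 SE > 0.125) the comparison is inconclusive. Hypothesis ranking
#' against explicit pedigrees is handed to [rank_hypotheses()].
#'
#' @param auto,x One-row `pk_kinship` slices for the same pair.
#' @param z_threshold Discordance threshold in combined SEs (default 2).
#' @return One-row tibble: `theta_auto`, `theta_x`, `diff`, `se_combined`,
#'   `z`, `verdict`.
#' @export
compare_auto_x <- function(auto, x, z_threshold = 2) {
  if (auto$degree == "insufficient-data" || x$degree == "insufficient-data") {
    stop_pk("both estimates must have sufficient data")
  }
  d <- x$theta - auto$theta
  se_c <- sqrt(auto$se^2 + x$se^2)
  z <- d / se_c
  verdict <- if (z_threshold * se_c > 0.125) "inconclusive"
  else if (z > z_threshold) "x-elevated (paternal-side candidate)"
  else if (z < -z_threshold) "x-reduced (maternal-side candidate)"
  else "concordant"
  tibble(id1 = auto$id1, id2 = auto$id2, theta_auto = auto$theta,
         theta_x = x$theta, diff = d, se_combined = se_c, z = z,
         verdict = verdict)
}
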