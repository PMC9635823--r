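#' Geodesic distance between coordinate pairs
#'
#' Haversine great-circle distance on a sphere of mean radius 6371.0088 km
#' (default), or ellipsoidal (WGS84) distance; the two differ by < 0.5%.
#'
#' @param lat1,lon1,lat2,lon2 Decimal degrees (vectorized).
#' @param method `"haversine"` (default) or `"ellipsoid"`.
#' @return Distance in km.
#' @export
geo_distance_km <- function(lat1, lon1, lat2, lon2,
                            method = c("haversine", "ellipsoid")) {
  method <- match.arg(method)
  p1 <- cbind(lon1, lat1); p2 <- cbind(lon2, lat2)
  if (method == "haversine") {
    geosphere::distHaversine(p1, p2, r = 6371008.8) / 1000
  } else {
    geosphere::distGeo(p1, p2) / 1000
  }
}

#' Filter set for isolation-by-distance pair tables
#'
#' The standard exclusions for distance-decay analysis: same-site pairs,
#' pairs more than 1000 years apart, pairs with fewer than 2000 overlapping
#' SNPs, and (optionally) close genetic kin.
#'
#' @param exclude_same_site Drop pairs from the same site.
#' @param max_year_gap Maximum |date difference| in years (`Inf` disables).
#' @param min_overlap Minimum overlapping SNPs.
#' @param exclude_close_kin Drop pairs flagged as close kin.
#' @return A filter specification list.
#' @export
ibd_filters <- function(exclude_same_site = TRUE, max_year_gap = 1000,
                        min_overlap = 2000, exclude_close_kin = FALSE) {
  list(exclude_same_site = exclude_same_site, max_year_gap = max_year_gap,
       min_overlap = min_overlap, exclude_close_kin = exclude_close_kin)
}

#' Build the per-pair analysis table
#'
#' Joins the (1 - f3) genetic dissimilarities with sample metadata and
#' kinship calls into one row per unordered pair: genetic distance,
#' geodesic km between sites, absolute date gap, same-site / same-building
#' flags and the close-kin flag. Pairs with missing coordinates are dropped
#' with a log message; an optional filter set (see [ibd_filters()]) is
#' applied afterwards.
#'
#' @param f3m A `pk_f3_matrix` from [pairwise_f3_matrix()].
#' @param meta Metadata tibble (`id`, `site`, `building`, `lat`, `lon`,
#'   `date_mean`).
#' @param kin Optional `pk_kinship` tibble; pairs classified
#'   identical/first/second/third become `close_kin`.
#' @param filters Optional [ibd_filters()] specification.
#' @param geo_method Passed to [geo_distance_km()].
#' @return Tibble with one row per retained pair.
#' @export
build_pair_table <- function(f3m, meta, kin = NULL, filters = NULL,
                             geo_method = "haversine") {
  pairs <- tidy.pk_f3_matrix(f3m)
  meta <- as_tibble(meta)
  need <- setdiff(unique(c(pairs$id1, pairs$id2)), meta$id)
  if (length(need) > 0) stop_pk("metadata missing for: ", paste(need, collapse = ", "))
  m1 <- meta[match(pairs$id1, meta$id), ]
  m2 <- meta[match(pairs$id2, meta$id), ]
  no_coord <- is.na(m1$lat) | is.na(m1$lon) | is.na(m2$lat) | is.na(m2$lon)
  if (any(no_coord)) {
    inform(paste0(sum(no_coord), " pair(s) dropped for missing coordinates"))
  }
  tb <- tibble(
    id1 = pairs$id1, id2 = pairs$id2,
    dist_gen = pairs$dist, n_overlap = pairs$n_overlap,
    dist_km = geo_distance_km(m1$lat, m1$lon, m2$lat, m2$lon, geo_method),
    gap_years = abs(m1$date_mean - m2$date_mean),
    site1 = m1$site, site2 = m2$site,
    same_site = m1$site == m2$site,
    building1 = if ("building" %in% names(m1)) m1$building else NA_character_,
    building2 = if ("building" %in% names(m2)) m2$building else NA_character_
  )
  tb$same_building <- !is.na(tb$building1) & !is.na(tb$building2) &
    tb$building1 == tb$building2
  tb$close_kin <- FALSE
  if (!is.null(kin)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    kk <- kin[kin$degree %in% c("identical", "first", "second", "third"), ]
    tb$close_kin <- key(tb$id1, tb$id2) %in% key(kk$id1, kk$id2)
  }
  tb <- tb[!no_coord, ]
  if (!is.null(filters)) {
    if (filters$exclude_same_site) tb <- tb[!tb$same_site, ]
    tb <- tb[!is.na(tb$dist_gen), ]
    tb <- tb[tb$gap_years <= filters$max_year_gap, ]
    tb <- tb[tb$n_overlap >= filters$min_overlap, ]
    if (filters$exclude_close_kin) tb <- tb[!tb$close_kin, ]
  }
  tb
}

#' Isolation-by-distance regression
#'
#' Ordinary least squares of genetic distance (1 - f3) on geodesic
#' distance. The reported p-value is the usual two-sided slope test; note
#' that pairs sharing an individual are not independent, so a
#' label-permutation check (see [residuals_by_group()]) is the more
#' defensible significance assessment.
#'
#' @param pairs A pair table from [build_pair_table()].
#' @return A `pk_ibd` object wrapping the [stats::lm()] fit.
#' @export
ibd_regression <- function(pairs) {
  if (nrow(pairs) < 3) stop_pk("need at least 3 pairs")
  if (var(pairs$dist_km) == 0) stop_pk("no variance in geographic distance")
  fit <- lm(dist_gen ~ dist_km, data = pairs)
  sm <- summary(fit)
  structure(list(
    fit = fit, pairs = pairs,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p = unname(sm$coefficients[2, 4]),
    residuals = unname(stats::residuals(fit))
  ), class = "pk_ibd")
}

#' @export
print.pk_ibd <- function(x, ...) {
  cat("<pk_ibd> ", nrow(x$pairs), " pairs: slope ",
      format(x$slope, digits = 4), " per km, R^2 ",
      format(x$r_squared, digits = 3), ", p ", format(x$p, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.pk_ibd <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.pk_ibd <- function(x, ...) {
  tibble(r.squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         p.value = x$p, n_pairs = nrow(x$pairs))
}

#' Group-wise residual analysis of the distance-decay fit
#'
#' For each group of pairs (e.g. pairs involving one population), reports
#' the median regression residual and a permutation p-value for
#' `|median residual|` under random reassignment of group labels across
#' pairs, with Benjamini-Hochberg adjustment across groups. A group sitting
#' above the regression line (positive median residual) is more
#' differentiated than its geographic separation predicts.
#'
#' @param ibd_fit A `pk_ibd` from [ibd_regression()].
#' @param groups Character vector of group labels, one per pair (in the
#'   order of `ibd_fit$pairs`).
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return Tibble with `group`, `n_pairs`, `median_resid`, `p`, `p_adj`.
#' @export
residuals_by_group <- function(ibd_fit, groups, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(ibd_fit, "pk_ibd"))
  res <- ibd_fit$residuals
  stopifnot(length(groups) == length(res))
  glev <- unique(groups)
  if (length(glev) < 2) {
    return(tibble(group = glev, n_pairs = length(res),
                  median_resid = median(res), p = 1, p_adj = 1))
  }
  obs <- vapply(glev, function(g) median(res[groups == g]), numeric(1))
  counts <- vapply(glev, function(g) sum(groups == g), integer(1))
  if (any(counts < 3)) {
    warn("groups with < 3 pairs have low-resolution permutation p-values")
  }
  with_seed(seed, {
    exceed <- numeric(length(glev))
    for (b in seq_len(n_perm)) {
      gp <- sample(groups)
      for (k in seq_along(glev)) {
        if (abs(median(res[gp == glev[k]])) >= abs(obs[k])) {
          exceed[k] <- exceed[k] + 1
        }
      }
    }
    p <- (exceed + 1) / (n_perm + 1)
    tibble(group = glev, n_pairs = counts, median_resid = unname(obs),
           p = p, p_adj = bh_adjust(p))
  })
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a symmetric dissimilarity matrix in `k` dimensions by
#' double-centering and eigendecomposition. Masked (low-overlap) entries
#' are imputed with the mean off-diagonal dissimilarity (with a warning) or
#' resolved by iteratively dropping the most-masked individuals. Axis signs
#' are fixed so the largest-magnitude coordinate on each axis is positive,
#' making output deterministic.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal (`NA` =
#'   masked), or a `pk_f3_matrix`.
#' @param k Number of dimensions (default 2; shrunk with a warning if
#'   positive eigenvalues run out).
#' @param impute `"mean"` (default) or `"drop"`.
#' @return A `pk_mds`: `points` (ids x k), `eig`, `k`, `dropped`.
#' @export
classical_mds <- function(d, k = 2, impute = c("mean", "drop")) {
  impute <- match.arg(impute)
  if (inherits(d, "pk_f3_matrix")) d <- d$dist
  if (!isSymmetric(unname(d))) stop_pk("dissimilarity matrix must be symmetric")
  if (any(diag(d) != 0, na.rm = TRUE)) stop_pk("diagonal must be zero")
  ids <- rownames(d) %||% paste0("i", seq_len(nrow(d)))
  dropped <- character()
  off <- d[upper.tri(d)]
  if (anyNA(off)) {
    if (impute == "mean") {
      warn(paste0(sum(is.na(off)), " masked dissimilarities imputed with the matrix mean"))
      d[is.na(d)] <- mean(off, na.rm = TRUE)
    } else {
      while (anyNA(d[upper.tri(d)])) {
        worst <- which.max(rowSums(is.na(d)))
        dropped <- c(dropped, ids[worst])
        d <- d[-worst, -worst, drop = FALSE]
        ids <- ids[-worst]
      }
    }
  }
  mds <- cmdscale(stats::as.dist(d), k = min(k, nrow(d) - 1), eig = TRUE)
  n_pos <- sum(mds$eig > 1e-12)
  if (n_pos < k) {
    warn(paste0("only ", n_pos, " positive eigenvalues; k shrunk from ", k))
    k <- max(1, n_pos)
  }
  pts <- mds$points[, seq_len(k), drop = FALSE]
  for (a in seq_len(ncol(pts))) {
    if (pts[which.max(abs(pts[, a])), a] < 0) pts[, a] <- -pts[, a]
  }
  rownames(pts) <- ids
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  structure(list(points = pts, eig = mds$eig, k = k, dropped = dropped),
            class = "pk_mds")
}

#' @export
print.pk_mds <- function(x, ...) {
  cat("<pk_mds> ", nrow(x$points), " points in ", x$k, " dimensions",
      if (length(x$dropped)) paste0(" (dropped: ", paste(x$dropped, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.pk_mds <- function(x, ...) {
  out <- as_tibble(x$points)
  out$id <- rownames(x$points)
  out[, c("id", setdiff(names(out), "id"))]
}
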