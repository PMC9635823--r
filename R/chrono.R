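#' Calibrated-age probability distribution
#'
#' A discrete probability mass function over integer calendar years
#' (cal BCE). Calibration itself is upstream of this package: grids are
#' consumed, not produced. Year differences are exact integers.
#'
#' @param year Integer calendar years (cal BCE), strictly ordered.
#' @param mass Non-negative probability masses; must sum to 1 (within 1e-9)
#'   unless `normalize = TRUE`.
#' @param normalize Rescale `mass` to sum to 1.
#' @return An `age_distribution`.
#' @export
age_distribution <- function(year, mass, normalize = FALSE) {
  if (length(year) != length(mass)) stop_pk("year and mass lengths differ")
  if (is.unsorted(year, strictly = TRUE) && is.unsorted(rev(year), strictly = TRUE)) {
    stop_pk("year grid must be strictly ordered")
  }
  if (any(mass < 0)) stop_pk("masses must be non-negative")
  s <- sum(mass)
  if (normalize) {
    if (s <= 0) stop_pk("total mass is zero")
    mass <- mass / s
  } else if (abs(s - 1) > 1e-9) {
    stop_pk("masses must sum to 1 (got ", format(s), "); use normalize = TRUE")
  }
  structure(list(year = as.integer(year), mass = mass), class = "age_distribution")
}

#' @export
print.age_distribution <- function(x, ...) {
  mu <- sum(x$year * x$mass)
  cat("<age_distribution> ", length(x$year), " years, mean ",
      round(mu), " cal BCE\n", sep = "")
  invisible(x)
}

#' Truncated-Gaussian age grid
#'
#' Builds a discretized, renormalized Gaussian age distribution — the
#' synthetic stand-in for a calibrated radiocarbon density.
#'
#' @param mean,sd Mean and SD in years cal BCE.
#' @param width Half-width of the grid in SDs (default 4).
#' @return An [age_distribution()].
#' @export
age_grid_gaussian <- function(mean, sd, width = 4) {
  years <- seq.int(round(mean - width * sd), round(mean + width * sd))
  m <- stats::dnorm(years, mean, sd)
  age_distribution(years, m / sum(m))
}

#' Sample calendar ages from a calibrated distribution
#'
#' @param dist An [age_distribution()].
#' @param n Number of draws (default 10000).
#' @param seed Optional integer seed.
#' @return Integer vector of sampled years (cal BCE).
#' @export
sample_ages <- function(dist, n = 10000, seed = NULL) {
  stopifnot(inherits(dist, "age_distribution"))
  with_seed(seed, {
    if (length(dist$year) == 1) rep(dist$year, n)
    else sample(dist$year, n, replace = TRUE, prob = dist$mass)
  })
}

#' Temporal-overlap test for a pair of dated individuals
#'
#' Samples ages from the two calibrated distributions (`n` times each,
#' default 10000), forms the per-replicate difference `draw1 - draw2`, and
#' reports its mean and 2.5%/97.5% quantiles. The pair is judged
#' "overlap-compatible" — the two individuals may have lived at the same
#' time — when the 95% interval contains 0.
#'
#' @param dist1,dist2 [age_distribution()]s.
#' @param n Number of resampling replicates.
#' @param seed Optional integer seed.
#' @return One-row tibble: `mean_diff`, `q2.5`, `q97.5`,
#'   `overlap_compatible`, `n`.
#' @export
pairwise_gap <- function(dist1, dist2, n = 10000, seed = NULL) {
  with_seed(seed, {
    d <- sample_ages(dist1, n) - sample_ages(dist2, n)
    q <- unname(quantile(d, c(0.025, 0.975), type = 1))
    tibble(mean_diff = mean(d), q2.5 = q[1], q97.5 = q[2],
           overlap_compatible = q[1] <= 0 && q[2] >= 0, n = n)
  })
}

#' Stacked summed probability distribution of calibrated dates
#'
#' Sums the members' age masses within each group and aggregates them into
#' consecutive calendar bins aligned to multiples of the bin width
#' (default 100 years). Total mass per group equals its number of
#' individuals.
#'
#' @param dists Named list of [age_distribution()]s.
#' @param bin_width Bin width in years (default 100).
#' @param grouping Named character vector mapping individual -> group;
#'   `NULL` puts everyone in one group.
#' @return Tibble with `group`, `bin_start` (year cal BCE, inclusive lower
#'   edge of `[bin_start, bin_start + bin_width)`), `mass`.
#' @export
spd_stack <- function(dists, bin_width = 100, grouping = NULL) {
  ids <- names(dists)
  if (is.null(ids)) stop_pk("dists must be a named list")
  grp <- if (is.null(grouping)) setNames(rep("all", length(ids)), ids) else grouping
  groups <- unique(unname(grp[ids]))
  out <- purrr::map_dfr(groups, function(gname) {
    members <- ids[grp[ids] %in% gname]
    if (length(members) == 0) {
      warn(paste0("empty group: ", gname))
      return(tibble(group = gname, bin_start = integer(), mass = numeric()))
    }
    df <- purrr::map_dfr(members, function(id) {
      a <- dists[[id]]
      tibble(bin_start = as.integer(floor(a$year / bin_width) * bin_width),
             mass = a$mass)
    })
    df %>%
      group_by(.data$bin_start) %>%
      summarise(mass = sum(.data$mass), .groups = "drop") %>%
      mutate(group = gname) %>%
      select("group", "bin_start", "mass")
  })
  out
}
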