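test_that("haversine distance matches the closed form on a meridian degree", {
  expect_equal(geo_distance_km(0, 0, 0, 1), 6371.0088 * pi / 180,
               tolerance = 1e-5)
  expect_equal(geo_distance_km(0, 0, 0, 1), 111.19, tolerance = 1e-4)
  # ellipsoidal option differs by < 0.5%
  h <- geo_distance_km(38, 39, 34, 44)
  e <- geo_distance_km(38, 39, 34, 44, method = "ellipsoid")
  expect_lt(abs(h - e) / e, 0.005)
})

make_pair_fixture <- function() {
  ids <- c("a", "b", "c", "d")
  d <- matrix(0.25, 4, 4, dimnames = list(ids, ids)); diag(d) <- 0
  ov <- matrix(5000, 4, 4); ov[1, 2] <- ov[2, 1] <- 1500  # a-b low overlap
  f3m <- structure(list(dist = d, f3 = 1 - d, overlap = ov, ids = ids,
                        min_overlap = 0), class = "pk_f3_matrix")
  meta <- tibble::tibble(
    id = ids, site = c("S1", "S1", "S2", "S3"),
    building = c("B1", "B1", NA, NA),
    lat = c(38, 38, 36, 35), lon = c(39, 39, 41, 43),
    date_mean = c(8300, 8300, 8250, 7000)  # d is 1250+ years from c
  )
  list(f3m = f3m, meta = meta)
}

test_that("pair-table filters drop same-site, distant-in-time and low-overlap pairs", {
  fx <- make_pair_fixture()
  full <- build_pair_table(fx$f3m, fx$meta)
  expect_equal(nrow(full), 6)
  expect_true(full$same_site[full$id1 == "a" & full$id2 == "b"])
  filt <- build_pair_table(fx$f3m, fx$meta, filters = ibd_filters())
  # a-b same site (and low overlap); any pair with d has gap > 1000 years
  expect_false(any(filt$same_site))
  expect_true(all(filt$gap_years <= 1000))
  expect_true(all(filt$n_overlap >= 2000))
  expect_setequal(paste(filt$id1, filt$id2),
                  c("a c", "b c"))
})

test_that("IBD regression is exact OLS with its degenerate guards", {
  km <- seq(100, 1000, by = 100)
  pairs <- tibble::tibble(id1 = "x", id2 = "y", dist_km = km,
                          dist_gen = 0.001 + 1e-6 * km)
  fit <- suppressWarnings(ibd_regression(pairs))
  expect_equal(fit$slope, 1e-6, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.001, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_lt(abs(mean(fit$residuals)), 1e-10 * sd(pairs$dist_gen))
  # closed-form OLS oracle on noisy data
  set.seed(61)
  pairs2 <- tibble::tibble(id1 = "x", id2 = "y", dist_km = runif(50, 0, 900),
                           dist_gen = 0.2 + 2e-5 * runif(50, 0, 900) + rnorm(50, 0, 0.01))
  f2 <- ibd_regression(pairs2)
  sl <- cov(pairs2$dist_km, pairs2$dist_gen) / var(pairs2$dist_km)
  expect_equal(f2$slope, sl, tolerance = 1e-10)
  expect_equal(f2$intercept, mean(pairs2$dist_gen) - sl * mean(pairs2$dist_km),
               tolerance = 1e-10)
  expect_error(ibd_regression(pairs[1:2, ]), "3 pairs")
  pairs$dist_km <- 5
  expect_error(ibd_regression(pairs), "variance")
})

test_that("group residual analysis handles the degenerate single group", {
  pairs <- tibble::tibble(id1 = "x", id2 = "y", dist_km = runif(20, 0, 500))
  pairs$dist_gen <- 0.2 + 1e-5 * pairs$dist_km + rnorm(20, 0, 0.005)
  fit <- ibd_regression(pairs)
  r1 <- residuals_by_group(fit, rep("all", 20), n_perm = 99, seed = 1)
  expect_equal(r1$p, 1)
  set.seed(62)
  r2 <- residuals_by_group(fit, sample(rep(c("g1", "g2"), 10)), n_perm = 199,
                           seed = 2)
  expect_true(all(r2$p >= 1 / 200))
  expect_true(all(r2$p_adj >= r2$p))
})

test_that("classical MDS reconstructs Euclidean configurations exactly", {
  # equilateral triangle with unit sides
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  m <- classical_mds(d3, k = 2)
  rec <- as.matrix(dist(m$points))
  expect_equal(unname(rec[upper.tri(rec)]), rep(1, 3), tolerance = 1e-9)

  set.seed(63)
  X <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(X))
  rownames(D) <- colnames(D) <- paste0("p", 1:10)
  m2 <- classical_mds(D, k = 2)
  expect_equal(unname(as.matrix(dist(m2$points))), unname(D), tolerance = 1e-9)
  # Procrustes-style check: centred configurations agree up to rotation
  A <- scale(X, scale = FALSE); B <- m2$points
  s <- svd(crossprod(B, A))
  R <- s$u %*% t(s$v)
  expect_lt(max(abs(B %*% R - A)), 1e-8)
  # deterministic sign convention
  expect_gt(m2$points[which.max(abs(m2$points[, 1])), 1], 0)

  # masked entries: mean imputation warns, drop mode removes individuals
  Dm <- D; Dm[1, 2] <- Dm[2, 1] <- NA
  expect_warning(classical_mds(Dm, k = 2), "imputed")
  md <- suppressWarnings(classical_mds(Dm, k = 2, impute = "drop"))
  expect_equal(nrow(md$points), 9)
  expect_length(md$dropped, 1)
})

test_that("diversity permutation contrasts within-site medians", {
  set.seed(64)
  ids <- paste0("i", 1:20)
  sites <- setNames(rep(c("S1", "S2"), each = 10), ids)
  prs <- t(combn(ids, 2))
  pairs <- tibble::tibble(id1 = prs[, 1], id2 = prs[, 2])
  both_s1 <- sites[pairs$id1] == "S1" & sites[pairs$id2] == "S1"
  both_s2 <- sites[pairs$id1] == "S2" & sites[pairs$id2] == "S2"
  # S1 strongly less diverse than S2
  pairs$dist_gen <- runif(nrow(pairs), 0.28, 0.32)
  pairs$dist_gen[both_s1] <- runif(sum(both_s1), 0.10, 0.12)
  pairs$dist_gen[both_s2] <- runif(sum(both_s2), 0.30, 0.32)
  dv <- diversity_permutation(pairs, sites, n_perm = 999, seed = 3)
  expect_equal(nrow(dv), 1)
  expect_lt(dv$median1, dv$median2)
  expect_equal(dv$p, 1 / 1000)  # most extreme observed, add-one bound
  # sites below the size threshold are excluded
  sites2 <- c(sites, i21 = "S3")
  expect_message(
    dv2 <- diversity_permutation(dplyr::bind_rows(
      pairs, tibble::tibble(id1 = "i1", id2 = "i21", dist_gen = 0.3)),
      sites2, n_perm = 99, seed = 4),
    "excluded")
  expect_error(diversity_permutation(pairs, sites[1:6], n_perm = 9), "2 sites")
})

test_that("coburial permutation rejects degenerate groupings and excludes kin", {
  ids <- paste0("i", 1:10)
  prs <- t(combn(ids, 2))
  pairs <- tibble::tibble(id1 = prs[, 1], id2 = prs[, 2],
                          dist_gen = 0.3, close_kin = FALSE)
  expect_error(coburial_permutation(pairs, setNames(rep("B1", 10), ids), 99),
               "2 buildings")
  # close-kin pairs do not contribute to the statistic
  b <- setNames(rep(c("B1", "B2"), each = 5), ids)
  pairs2 <- pairs
  w_in <- b[pairs2$id1] == b[pairs2$id2]
  pairs2$dist_gen[w_in] <- 0.2
  pairs2$dist_gen[pairs2$id1 == "i1" & pairs2$id2 == "i2"] <- 0.0001
  pairs2$close_kin[pairs2$id1 == "i1" & pairs2$id2 == "i2"] <- TRUE
  r <- coburial_permutation(pairs2, b, n_perm = 199, seed = 5)
  # effect size computed on non-kin pairs only: 0.3 - 0.2
  expect_equal(r$effect_size, 0.1, tolerance = 1e-12)
  expect_lt(r$p, 0.05)
  expect_equal(r$sided, "one-sided (within closer)")
})
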