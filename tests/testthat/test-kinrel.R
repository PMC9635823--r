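test_that("windowed P0 counts mismatches among co-called sites", {
  # 10 SNPs in one 1-Mb window: 8 co-called, 3 mismatching
  a <- c(2L, 2L, 2L, 0L, 0L, 0L, 2L, 0L, NA, 2L)
  b <- c(2L, 0L, 2L, 0L, 2L, 0L, 2L, 2L, 2L, NA)
  g <- toy_geno(cbind(a, b), spacing = 1e4)
  w <- windowed_p0(g, c("ind1", "ind2"))
  expect_equal(nrow(w), 1)
  expect_equal(w$n_overlap, 8L)
  expect_equal(w$n_mismatch, 3L)
  expect_equal(w$p0, 0.375)

  # identical call vectors -> all P0 = 0; complementary -> all P0 = 1
  gi <- toy_geno(cbind(a, a), spacing = 1e4)
  expect_equal(windowed_p0(gi, c("ind1", "ind2"))$p0, 0)
  gc <- toy_geno(cbind(rep(2L, 10), rep(0L, 10)), spacing = 1e4)
  expect_equal(windowed_p0(gc, c("ind1", "ind2"))$p0, 1)

  gd <- toy_geno(matrix(c(1L, 0L, 1L, 0L), 2, 2), pseudo = c(FALSE, FALSE))
  expect_error(windowed_p0(gd, c("ind1", "ind2")), "pseudo-haploid")
})

test_that("P0 normalization uses the median as an unrelated baseline", {
  nm <- normalize_p0(c(0.24, 0.25, 0.26, 0.1875))
  expect_equal(nm$baseline, 0.245)
  nm2 <- normalize_p0(c(0.24, 0.25, 0.26))
  expect_equal(nm2$baseline, 0.25)
  expect_equal(normalize_p0(0.1875, "fixed", baseline = 0.25)$normalized, 0.75)
  # all pairs equal -> theta = 0 everywhere
  nm3 <- normalize_p0(rep(0.25, 5))
  expect_equal(1 - nm3$normalized, rep(0, 5))
  # fixed baseline reproduces median mode
  nm4 <- normalize_p0(c(0.24, 0.25, 0.26), "fixed", baseline = 0.25)
  expect_equal(nm4$normalized, nm2$normalized)
  expect_error(normalize_p0(c(0.1, 0.2), "median"), "3 pairs")
  expect_error(normalize_p0(0.2, "fixed", baseline = 0), "non-zero")
})

test_that("degree classification uses midpoint bins, |Z| > 2 and SNP thresholds", {
  c1 <- classify_degree(0.75, se = 1e-4, n_snps = 5000)
  expect_equal(as.character(c1$degree), "first")
  # |Z| = 1: demoted to unrelated
  c2 <- classify_degree(0.95, se = 0.05, n_snps = 5000)
  expect_equal(as.character(c2$degree), "unrelated")
  # insufficient overlap dominates
  c3 <- classify_degree(0.75, se = 1e-4, n_snps = 1500)
  expect_equal(as.character(c3$degree), "insufficient-data")
  c4 <- classify_degree(0.9, se = 1e-4, n_snps = 150, min_snps = 200)
  expect_equal(as.character(c4$degree), "insufficient-data")
  # bin edges
  cls <- classify_degree(c(0.5, 0.7, 0.85, 0.93, 0.99), se = rep(1e-4, 5),
                         n_snps = rep(5000, 5))
  expect_equal(as.character(cls$degree),
               c("identical", "first", "second", "third", "unrelated"))
})

test_that("theta follows the nine-coefficient Jaccard formula", {
  expect_equal(theta_from_jaccard(c(1, rep(0, 8))), 1)
  expect_equal(theta_from_jaccard(c(rep(0, 7), 1, 0)), 0.25)
  expect_equal(theta_from_jaccard(c(0, 1, rep(0, 7))), 0)
  j <- c(0.1, 0.1, 0.2, 0.1, 0.2, 0.1, 0.1, 0.05, 0.05)
  expect_equal(theta_from_jaccard(j), 0.1 + 0.5 * (0.2 + 0.2 + 0.1) + 0.25 * 0.05)
  expect_error(theta_from_jaccard(rep(0.2, 9)), "sum to 1")
})

test_that("kinship estimates are symmetric and invariant to SNP order", {
  sim <- suppressMessages(simulate_dataset(sim_config(n_snps = 4000), seed = 13))
  ids <- c("child1", "gaunt", "fa1", "target_1")
  k1 <- kinship_read(sim$geno, ids = ids, min_snps = 100)
  k2 <- kinship_read(sim$geno, ids = rev(ids), min_snps = 100)
  key <- function(k) paste(pmin(k$id1, k$id2), pmax(k$id1, k$id2))
  m <- match(key(k1), key(k2))
  expect_equal(k1$theta, k2$theta[m], tolerance = 1e-12)
  # permuting SNP rows within chromosomes changes nothing (windows are
  # position-defined)
  ord <- order(sim$geno$snp$chrom, sim$geno$snp$physical_pos)
  g3 <- subset_geno(sim$geno, snps = ord)
  k3 <- kinship_read(g3, ids = ids, min_snps = 100)
  expect_equal(k1$theta, k3$theta[match(key(k1), key(k3))], tolerance = 1e-12)
})

test_that("identical pairs are detected, merged, and chains are unified", {
  sim <- suppressMessages(simulate_dataset(sim_config(n_snps = 9000), seed = 14))
  tgt <- sim$meta$id[sim$meta$population == "target"]
  kin <- kinship_read(sim$geno, ids = tgt, min_snps = 1000)
  det <- detect_identicals(kin)
  expect_equal(nrow(det), 1)
  expect_equal(sort(det$ids[[1]]), c("tw1", "tw1_dup"))
  merged <- suppressMessages(merge_identicals(sim$geno, det))
  mid <- det$merged_id[1]
  expect_true(mid %in% merged$ind$id)
  expect_false(any(c("tw1", "tw1_dup") %in% merged$ind$id))
  # union property: merged coverage is at least each constituent's
  cov_merged <- sum(!is.na(merged$calls[, mid]))
  expect_gte(cov_merged, sum(!is.na(sim$geno$calls[, "tw1"])))
  expect_gte(cov_merged, sum(!is.na(sim$geno$calls[, "tw1_dup"])))
  # conflicting co-called sites are set missing
  log <- attr(merged, "merge_log")
  both <- !is.na(sim$geno$calls[, "tw1"]) & !is.na(sim$geno$calls[, "tw1_dup"])
  confl <- both & sim$geno$calls[, "tw1"] != sim$geno$calls[, "tw1_dup"]
  expect_equal(log$n_conflict, sum(confl))
  expect_true(all(is.na(merged$calls[confl, mid])))

  # chained identity: A=B, B=C significant, A-C insufficient -> one group of 3
  est <- tibble::tibble(id1 = c("A", "B", "A"), id2 = c("B", "C", "C"),
                        degree = factor(c("identical", "identical",
                                          "insufficient-data")))
  expect_warning(d3 <- detect_identicals(est), "chained")
  expect_equal(sort(d3$ids[[1]]), c("A", "B", "C"))

  # unrelated pairs are never flagged
  unrel <- kin[kin$theta < 0.3, ]
  expect_equal(nrow(detect_identicals(unrel)), 0)
})

test_that("autosomal-vs-X comparison flags paternal-side discordance", {
  row_of <- function(theta, se, id1 = "a", id2 = "b") {
    tibble::tibble(id1 = id1, id2 = id2, theta = theta, se = se,
                   degree = factor("third"))
  }
  r <- compare_auto_x(row_of(0.0625, 0.01), row_of(0.1875, 0.03))
  expect_match(r$verdict, "paternal")
  r2 <- compare_auto_x(row_of(0.0625, 0.01), row_of(0.0625, 0.015))
  expect_equal(r2$verdict, "concordant")
  r3 <- compare_auto_x(row_of(0.0625, 0.2), row_of(0.1875, 0.2))
  expect_equal(r3$verdict, "inconclusive")
  expect_error(
    compare_auto_x(row_of(0.0625, 0.01),
                   tibble::tibble(id1 = "a", id2 = "b", theta = 0.1, se = 0.01,
                                  degree = factor("insufficient-data"))),
    "sufficient data")
})

test_that("X-chromosome kinship separates maternal from paternal first degree", {
  cfg <- sim_config(n_snps = 24000, missingness = 0.9, error_rate = 0.002)
  sim <- suppressMessages(simulate_dataset(cfg, seed = 15))
  tgt <- sim$meta$id[sim$meta$population == "target"]
  kx <- kinship_read(sim$geno, ids = tgt, chrom_class = "X")
  expect_true(all(kx$chrom_class == "X"))
  pick <- function(k, a, b) k[(k$id1 == a & k$id2 == b) | (k$id1 == b & k$id2 == a), ]
  ms <- pick(kx, "mo1", "child2")     # mother-son: theta_X = 0.5
  fs <- pick(kx, "fa1", "child2")     # father-son: theta_X = 0
  expect_lt(abs(ms$theta - 0.5), 3 * ms$se)
  expect_lt(abs(fs$theta - 0), 3 * fs$se)
  # X SNP-count rule: a pair with < 200 overlapping X SNPs is insufficient
  sim2 <- suppressMessages(simulate_dataset(sim_config(n_snps = 2000), seed = 16))
  kx2 <- kinship_read(sim2$geno, ids = tgt, chrom_class = "X")
  expect_true(all(kx2$degree[kx2$n_snps <= 200] == "insufficient-data"))
  expect_true(any(kx2$degree == "insufficient-data"))
})

test_that("PAR-masked X SNPs are excluded from X analyses", {
  snp <- toy_snp(10, chrom = "X")
  snp$par <- c(rep(TRUE, 3), rep(FALSE, 7))
  g <- geno_matrix(matrix(2L, 10, 2), snp,
                   tibble::tibble(id = c("a", "b"), sex = c("F", "F"),
                                  population = "p", pseudo_haploid = TRUE))
  gx <- chrom_class_geno(g, "X")
  expect_equal(nrow(gx$snp), 7)
  expect_false(any(gx$snp$par))
})

test_that("the median baseline is robust to a planted minority of relatives", {
  sim <- suppressMessages(simulate_dataset(sim_config(n_snps = 12000), seed = 17))
  tgt <- sim$meta$id[sim$meta$population == "target"]
  kin_med <- kinship_read(sim$geno, ids = tgt, min_snps = 1000)
  # oracle baseline: median P0 over truly unrelated pairs only
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tr <- sim$truth$relations
  related <- key(kin_med$id1, kin_med$id2) %in% key(tr$id1, tr$id2)
  oracle_base <- median(kin_med$p0[!related])
  kin_fix <- kinship_read(sim$geno, ids = tgt, min_snps = 1000,
                          baseline = oracle_base)
  shift <- abs(kin_med$theta[!related] - kin_fix$theta[!related])
  expect_lt(max(shift), 0.02)
})
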