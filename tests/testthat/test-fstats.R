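test_that("allele frequencies pool allele copies by ploidy", {
  # two pseudo-haploid calls 2 and 0 -> p = 0.5 over 2 alleles
  g <- toy_geno(matrix(c(2L, NA, 0L, NA), 2, 2))
  fr <- allele_freqs(g, grouping = c(ind1 = "A", ind2 = "A"))
  expect_equal(unname(fr$p[1, "A"]), 0.5)
  expect_equal(unname(fr$n[1, "A"]), 2)
  # all missing -> p missing
  expect_true(is.na(fr$p[2, "A"]))
  expect_equal(unname(fr$n[2, "A"]), 0)
  # one diploid het call -> p = 0.5, n = 2
  gd <- toy_geno(matrix(1L, 1, 1), pseudo = FALSE)
  frd <- allele_freqs(gd, grouping = c(ind1 = "B"))
  expect_equal(unname(frd$p[1, "B"]), 0.5)
  expect_equal(unname(frd$n[1, "B"]), 2)
})

test_that("outgroup f3 matches hand arithmetic and is symmetric", {
  ft <- toy_freq_table(cbind(O = c(1, 0), A = c(0.5, 0.5), B = c(0.5, 0.5)))
  expect_equal(f3_outgroup(ft, "O", "A", "B")$estimate, 0.25)
  set.seed(2)
  ft2 <- toy_freq_table(cbind(O = runif(200), A = runif(200), B = runif(200)))
  expect_identical(f3_outgroup(ft2, "O", "A", "B")$estimate,
                   f3_outgroup(ft2, "O", "B", "A")$estimate)
  expect_gte(f3_outgroup(ft2, "O", "A", "A")$estimate, 0)
})

test_that("f3, D and f4 equal an independent brute-force loop to 1e-12", {
  set.seed(42)
  n <- 1000
  pm <- cbind(W = runif(n), X = runif(n), Y = runif(n), Z = runif(n))
  pm[sample(length(pm), 150)] <- NA  # exercise per-statistic SNP sets
  ft <- toy_freq_table(pm)

  brute_f3 <- local({
    tot <- 0; k <- 0
    for (i in seq_len(n)) {
      if (anyNA(pm[i, c("W", "X", "Y")])) next
      tot <- tot + (pm[i, "W"] - pm[i, "X"]) * (pm[i, "W"] - pm[i, "Y"])
      k <- k + 1
    }
    unname(tot / k)
  })
  expect_equal(f3_outgroup(ft, "W", "X", "Y")$estimate, brute_f3,
               tolerance = 1e-12)

  brute_f4 <- local({
    tot <- 0; k <- 0
    for (i in seq_len(n)) {
      if (anyNA(pm[i, ])) next
      tot <- tot + (pm[i, "W"] - pm[i, "X"]) * (pm[i, "Y"] - pm[i, "Z"])
      k <- k + 1
    }
    unname(tot / k)
  })
  expect_equal(f4_statistic(ft, "W", "X", "Y", "Z")$estimate, brute_f4,
               tolerance = 1e-12)

  brute_d <- local({
    num <- 0; den <- 0
    for (i in seq_len(n)) {
      if (anyNA(pm[i, ])) next
      w <- pm[i, "W"]; x <- pm[i, "X"]; y <- pm[i, "Y"]; z <- pm[i, "Z"]
      num <- num + (w - x) * (y - z)
      den <- den + (w + x - 2 * w * x) * (y + z - 2 * y * z)
    }
    unname(num / den)
  })
  expect_equal(d_statistic(ft, "W", "X", "Y", "Z")$estimate, brute_d,
               tolerance = 1e-12)
})

test_that("D-statistic has its defining sign and degeneracy properties", {
  n <- 50
  ft1 <- toy_freq_table(cbind(W = rep(1, n), X = rep(0, n),
                              Y = rep(1, n), Z = rep(0, n)))
  expect_equal(d_statistic(ft1, "W", "X", "Y", "Z")$estimate, 1)
  set.seed(3)
  pm <- cbind(W = runif(n), X = runif(n), Y = runif(n), Z = runif(n))
  ft2 <- toy_freq_table(cbind(pm, Y2 = pm[, "Y"]))
  expect_equal(d_statistic(ft2, "W", "X", "Y", "Y2")$estimate, 0)
  expect_equal(d_statistic(ft2, "W", "X", "Y", "Z")$estimate,
               -d_statistic(ft2, "W", "X", "Z", "Y")$estimate)
})

test_that("weighted block jackknife reduces to the classical SE and scales", {
  set.seed(9)
  x <- rnorm(400)
  # singleton blocks: exact classical SE of the mean
  jk <- block_jackknife(x, blocks = seq_along(x))
  expect_equal(jk$se, sd(x) / sqrt(length(x)), tolerance = 1e-10)
  # identical leave-one-out estimates give SE 0
  jk0 <- block_jackknife(rep(1, 100), blocks = rep(1:10, each = 10))
  expect_equal(jk0$se, 0)
  # duplicating every block approximately halves SE^2 (brute-force recomputation)
  blocks <- rep(1:20, each = 20)
  jk1 <- block_jackknife(x, blocks = blocks)
  x2 <- c(x, x); blocks2 <- c(blocks, blocks + 20)
  jk2 <- block_jackknife(x2, blocks = blocks2)
  expect_equal(jk2$se^2 / jk1$se^2, 0.5, tolerance = 0.06)
  expect_error(block_jackknife(x, blocks = rep(1, length(x))), "2 non-empty")
})

test_that("BH adjustment equals a from-scratch step-up oracle", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  set.seed(4)
  for (rep in 1:5) {
    p <- runif(20)^2
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pairwise (1 - f3) matrix matches per-pair recomputation and masks", {
  sim <- suppressMessages(simulate_dataset(
    sim_config(n_snps = 1500, pedigrees = list(),
               identical_pairs = tibble::tibble(src = character(), copy = character()),
               buildings = NULL),
    seed = 8))
  ids <- sim$meta$id[sim$meta$population %in% c("anatolia", "zagros")][1:4]
  fm <- pairwise_f3_matrix(sim$geno, "outgroup", individuals = ids,
                           min_overlap = 100)
  expect_true(isSymmetric(unname(fm$dist)))
  expect_equal(unname(diag(fm$dist)), rep(0, 4))
  # brute-force per-pair f3 with per-pair SNP sets
  fr_o <- allele_freqs(subset_geno(sim$geno,
                                   inds = sim$meta$id[sim$meta$population == "outgroup"]),
                       grouping = setNames(rep("O", 6),
                                           sim$meta$id[sim$meta$population == "outgroup"]))
  fr_i <- allele_freqs(sim$geno, grouping = "individual")
  for (a in 1:3) for (b in (a + 1):4) {
    po <- fr_o$p[, "O"]; pa <- fr_i$p[, ids[a]]; pb <- fr_i$p[, ids[b]]
    use <- !is.na(po) & !is.na(pa) & !is.na(pb)
    expect_equal(fm$f3[a, b], mean(((po - pa) * (po - pb))[use]),
                 tolerance = 1e-12)
    expect_equal(fm$overlap[a, b], sum(use))
  }
  # masking below the overlap threshold
  fm2 <- pairwise_f3_matrix(sim$geno, "outgroup", individuals = ids,
                            min_overlap = max(fm$overlap[upper.tri(fm$overlap)]) + 1)
  expect_true(all(is.na(fm2$dist[upper.tri(fm2$dist)])))
  expect_equal(unname(diag(fm2$dist)), rep(0, 4))
})

test_that("Z, SE and estimate are mutually consistent", {
  set.seed(12)
  ft <- toy_freq_table(cbind(O = runif(300), A = runif(300), B = runif(300)))
  r <- f3_outgroup(ft, "O", "A", "B")
  expect_equal(abs(r$z) * r$se, abs(r$estimate), tolerance = 1e-12)
})
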