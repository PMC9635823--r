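# qpAdm-style admixture modeling.
#
# The target's allele frequencies are modelled as a weighted mixture of the
# source ("left") populations', and the fit is judged against a set of
# reference ("right") populations differentially related to the sources.
# The working statistics are f4(l, r_base; r_j, r_base) for every left
# population l and every non-base right population r_j: because f4 is
# bilinear in allele frequencies, an exact mixture target makes the residual
# t - A w vanish in expectation for the true weights w (sum w = 1), whatever
# base population is used. Estimation minimizes the quadratic form of the
# residual under its block-jackknife covariance.

#' Build the f4 statistic matrix for admixture modeling
#'
#' Computes `f4(l, base; r_j, base)` for every left population (target
#' first, then sources) against every non-base right population, together
#' with per-block sums so that leave-one-block-out replicates of every cell
#' are available downstream. Per-statistic SNP sets are the default
#' ("allsnps" behaviour: each cell uses every SNP where its four
#' populations have data); `allsnps = FALSE` restricts all cells to the
#' common intersection.
#'
#' @param freqs A `freq_table` from [allele_freqs()].
#' @param target Target population label.
#' @param sources Source ("left") population labels.
#' @param right Reference ("right") population labels; the first is the
#'   base.
#' @param block_span Jackknife block length in bp (default 5e6).
#' @param allsnps Per-statistic SNP sets (default `TRUE`).
#' @return A `pk_f4matrix` list: `est` ((1+n_sources) x (n_right-1) matrix
#'   of f4 estimates, target row first), block-sum arrays, SNP counts, and
#'   the population labels.
#' @export
build_f4_matrix <- function(freqs, target, sources, right, block_span = 5e6,
                            allsnps = TRUE) {
  if (length(right) < 3) stop_pk("need at least 3 right populations (base + 2)")
  left <- c(target, sources)
  overlap_lr <- intersect(left, right)
  if (length(overlap_lr) > 0) {
    stop_pk("populations cannot be both left and right: ",
            paste(overlap_lr, collapse = ", "))
  }
  base <- right[1]
  rj <- right[-1]
  pm <- get_freq_cols(freqs, c(left, right))
  blocks_all <- block_scheme(freqs$snp, block_span)
  if (!allsnps) {
    keep <- complete.cases(pm)
    pm <- pm[keep, , drop = FALSE]
    blocks_all <- blocks_all[keep]
  }
  ub <- sort(unique(blocks_all))
  g <- length(ub)
  if (g < 2) stop_pk("need at least 2 jackknife blocks")
  bidx <- match(blocks_all, ub)
  nl <- length(left); nr <- length(rj)
  S <- array(0, c(g, nl, nr), dimnames = list(NULL, left, rj))
  Cn <- array(0, c(g, nl, nr), dimnames = list(NULL, left, rj))
  pb <- pm[, base]
  for (i in seq_len(nl)) {
    dl <- pm[, left[i]] - pb
    for (j in seq_len(nr)) {
      dr <- pm[, rj[j]] - pb
      term <- dl * dr
      use <- !is.na(term)
      if (!any(use)) {
        stop_pk("empty SNP set for cell f4(", left[i], ", ", base, "; ",
                rj[j], ", ", base, ")")
      }
      S[, i, j] <- rowsum_safe(term[use], bidx[use], g)
      Cn[, i, j] <- rowsum_safe(rep(1, sum(use)), bidx[use], g)
    }
  }
  tot_S <- apply(S, c(2, 3), sum)
  tot_C <- apply(Cn, c(2, 3), sum)
  structure(list(
    est = tot_S / tot_C, S = S, C = Cn, n_snps = tot_C,
    target = target, sources = sources, right = right, base = base,
    n_blocks = g, block_span = block_span, allsnps = allsnps
  ), class = "pk_f4matrix")
}

rowsum_safe <- function(x, idx, g) {
  out <- numeric(g)
  rs <- rowsum(x, idx)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

#' @export
print.pk_f4matrix <- function(x, ...) {
  cat("<pk_f4matrix> target ", x$target, ", ", length(x$sources),
      " sources x ", length(x$right) - 1, " right contrasts (base ", x$base,
      "), ", x$n_blocks, " blocks\n", sep = "")
  invisible(x)
}

# Leave-one-block-out estimate matrices: list of g matrices (nl x nr).
f4_loo <- function(fm) {
  tot_S <- apply(fm$S, c(2, 3), sum)
  tot_C <- apply(fm$C, c(2, 3), sum)
  lapply(seq_len(fm$n_blocks), function(b) {
    (tot_S - fm$S[b, , ]) / (tot_C - fm$C[b, , ])
  })
}

# Constrained GLS: minimize (t - A'w)' Omega (t - A'w) s.t. sum(w) = 1,
# where rows of est are [target; sources].
solve_weights <- function(est, Omega) {
  tvec <- est[1, ]
  A <- t(est[-1, , drop = FALSE])     # m x ns
  ns <- ncol(A)
  G <- solve(crossprod(A, Omega %*% A))
  wu <- G %*% crossprod(A, Omega %*% tvec)
  one <- rep(1, ns)
  drop(wu + G %*% one %*% ((1 - sum(wu)) / drop(crossprod(one, G %*% one))))
}

residual_vec <- function(est, w) est[1, ] - drop(w %*% est[-1, , drop = FALSE])

# Jackknife covariance of the residual statistic vector at fixed weights.
residual_cov <- function(loo, w) {
  R <- t(vapply(loo, residual_vec, numeric(ncol(loo[[1]])), w = w))
  g <- nrow(R)
  Rc <- sweep(R, 2, colMeans(R))
  crossprod(Rc) * (g - 1) / g
}

regularize <- function(M) {
  if (!all(is.finite(M))) stop_pk("non-finite covariance")
  k <- tryCatch(kappa(M, exact = FALSE), error = function(e) Inf)
  if (!is.finite(k) || k > 1e12) {
    inform("near-singular jackknife covariance; ridge-regularizing")
    M <- M + diag(1e-10 * max(sum(diag(M)), 1e-12), nrow(M))
  }
  M
}

#' Fit admixture weights (qpAdm-style)
#'
#' Estimates mixture weights for the target as the minimizer of
#' `(t - A w)' Sigma^-1 (t - A w)` subject to `sum(w) = 1`, where `t` is
#' the target's f4 row, `A` the sources' rows and `Sigma` the
#' block-jackknife covariance of the residual statistics (weight-dependent,
#' so the GLS solve is iterated to convergence). The minimized quadratic
#' form is the model chi-square with
#' `dof = (n_right - 1) - (n_sources - 1)`; weight standard errors come
#' from leave-one-block-out refits. A near-singular covariance is
#' ridge-regularized with a logged warning.
#'
#' @param fm A `pk_f4matrix` from [build_f4_matrix()].
#' @param max_iter,tol GLS iteration controls.
#' @return A `pk_qpadm` object: weights, SEs, chi-square, dof, p-value,
#'   per-cell SNP counts, feasibility.
#' @export
fit_admixture <- function(fm, max_iter = 20, tol = 1e-10) {
  stopifnot(inherits(fm, "pk_f4matrix"))
  ns <- length(fm$sources)
  m <- ncol(fm$est)
  if (ns >= length(fm$right)) {
    stop_pk("need n_sources < n_right (", ns, " sources, ",
            length(fm$right), " right populations)")
  }
  loo <- f4_loo(fm)
  w <- rep(1 / ns, ns)
  for (it in seq_len(max_iter)) {
    Sigma <- regularize(residual_cov(loo, w))
    Omega <- solve(Sigma)
    w_new <- solve_weights(fm$est, Omega)
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  Sigma <- regularize(residual_cov(loo, w))
  Omega <- solve(Sigma)
  r <- residual_vec(fm$est, w)
  chisq <- max(0, drop(t(r) %*% Omega %*% r))
  dof <- (m) - (ns - 1)
  p <- pchisq(chisq, dof, lower.tail = FALSE)
  # jackknife SEs: refit on each leave-one-block-out matrix at fixed Omega
  W <- t(vapply(loo, solve_weights, numeric(ns), Omega = Omega))
  g <- nrow(W)
  se <- sqrt(colSums(sweep(W, 2, colMeans(W))^2) * (g - 1) / g)
  weights <- setNames(drop(w), fm$sources)
  structure(list(
    target = fm$target, sources = fm$sources, right = fm$right,
    weights = weights, se = setNames(se, fm$sources),
    chisq = chisq, dof = dof, p = p,
    n_snps = fm$n_snps, n_blocks = fm$n_blocks, allsnps = fm$allsnps,
    feasible = p > 0.05 && all(weights >= 0 & weights <= 1),
    base = fm$base
  ), class = "pk_qpadm")
}

#' @export
print.pk_qpadm <- function(x, ...) {
  cat("<pk_qpadm> ", x$target, " ~ ", paste(x$sources, collapse = " + "),
      "\n", sep = "")
  for (s in x$sources) {
    cat(sprintf("  %-14s %6.3f +/- %.3f\n", s, x$weights[s], x$se[s]))
  }
  cat(sprintf("  chi-square %.2f on %d dof, p = %.3g; %s\n",
              x$chisq, x$dof, x$p,
              if (x$feasible) "feasible" else "not feasible"))
  invisible(x)
}

#' @export
tidy.pk_qpadm <- function(x, ...) {
  tibble(term = x$sources, estimate = unname(x$weights),
         std.error = unname(x$se))
}

#' @export
glance.pk_qpadm <- function(x, ...) {
  tibble(chisq = x$chisq, dof = x$dof, p.value = x$p,
         n_right = length(x$right), n_blocks = x$n_blocks,
         feasible = x$feasible)
}

#' Classify the feasibility of a fitted admixture model
#'
#' A model is `feasible` when its tail p-value exceeds 0.05, `marginal`
#' when 0.01 < p <= 0.05, and `rejected` otherwise; any weight outside
#' `[0, 1]` flags the model infeasible regardless of p.
#'
#' @param model A `pk_qpadm` from [fit_admixture()].
#' @param alpha Feasibility and marginality thresholds (default 0.05,
#'   0.01).
#' @return One-row tibble: `classification`, `p`, `weights_in_range`,
#'   `feasible`.
#' @export
feasibility_report <- function(model, alpha = c(0.05, 0.01)) {
  stopifnot(inherits(model, "pk_qpadm"))
  cls <- if (model$p > alpha[1]) "feasible"
         else if (model$p > alpha[2]) "marginal"
         else "rejected"
  in_range <- all(model$weights >= 0 & model$weights <= 1)
  tibble(target = model$target, classification = cls, p = model$p,
         weights_in_range = in_range,
         feasible = cls == "feasible" && in_range)
}
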