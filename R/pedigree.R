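#' Pedigree constructor
#'
#' A sexed directed-ancestry graph. Every member has either both parents in
#' the pedigree or neither (founders); fathers must be male and mothers
#' female, and the graph must be acyclic.
#'
#' @param members Data frame with columns `id`, `sex` (`"M"`/`"F"`, also
#'   accepts `"male"`/`"female"`), `father`, `mother` (`NA` for founders).
#' @return A `pk_pedigree` tibble with a generation-`depth` column
#'   (founders 0).
#' @export
pedigree <- function(members) {
  m <- as_tibble(members)
  stopifnot(all(c("id", "sex", "father", "mother") %in% names(m)))
  m$sex <- dplyr::recode(tolower(as.character(m$sex)), male = "M", female = "F",
                         m = "M", f = "F")
  if (!all(m$sex %in% c("M", "F"))) stop_pk("sex must be male/M or female/F")
  if (anyDuplicated(m$id)) stop_pk("duplicate pedigree ids")
  one_parent <- xor(is.na(m$father), is.na(m$mother))
  if (any(one_parent)) {
    stop_pk("member ", m$id[one_parent][1],
            " has exactly one parent specified (must be both or none)")
  }
  for (col in c("father", "mother")) {
    known <- !is.na(m[[col]])
    bad <- !(m[[col]][known] %in% m$id)
    if (any(bad)) stop_pk("unknown ", col, ": ", m[[col]][known][bad][1])
  }
  fsex <- m$sex[match(m$father, m$id)]
  msex <- m$sex[match(m$mother, m$id)]
  if (any(fsex == "F", na.rm = TRUE)) stop_pk("a father is female")
  if (any(msex == "M", na.rm = TRUE)) stop_pk("a mother is male")

  depth <- rep(NA_integer_, nrow(m))
  depth[is.na(m$father)] <- 0L
  for (iter in seq_len(nrow(m) + 1)) {
    todo <- which(is.na(depth))
    if (length(todo) == 0) break
    if (iter > nrow(m)) stop_pk("pedigree contains a cycle")
    for (i in todo) {
      df <- depth[match(m$father[i], m$id)]
      dm <- depth[match(m$mother[i], m$id)]
      if (!is.na(df) && !is.na(dm)) depth[i] <- max(df, dm) + 1L
    }
  }
  if (any(is.na(depth))) stop_pk("pedigree contains a cycle")
  m$depth <- depth
  class(m) <- c("pk_pedigree", class(m))
  m
}

ped_index <- function(ped, id) {
  i <- match(id, ped$id)
  if (is.na(i)) stop_pk("id not in pedigree: ", id)
  i
}

#' Autosomal pedigree kinship coefficient
#'
#' The standard recursive kinship coefficient: the probability that one
#' allele drawn at random from each of `a` and `b` is identical by descent.
#' Founders are unrelated and non-inbred; `phi(a, a) = (1 + f_a) / 2` and
#' the recursion expands the individual farther from the founders through
#' its parents.
#'
#' @param ped A [pedigree()].
#' @param a,b Member ids.
#' @return Kinship coefficient in `[0, 1]`.
#' @export
kinship_auto <- function(ped, a, b) {
  stopifnot(inherits(ped, "pk_pedigree"))
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste0(i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      fa <- ped$father[i]
      if (is.na(fa)) 0.5
      else 0.5 * (1 + phi(ped_index(ped, fa), ped_index(ped, ped$mother[i])))
    } else {
      # expand the deeper member (never an ancestor of the shallower one)
      d <- if (ped$depth[i] >= ped$depth[j]) i else j
      o <- if (d == i) j else i
      if (is.na(ped$father[d])) 0
      else 0.5 * (phi(ped_index(ped, ped$father[d]), o) +
                    phi(ped_index(ped, ped$mother[d]), o))
    }
    memo[[key]] <- val
    val
  }
  phi(ped_index(ped, a), ped_index(ped, b))
}

#' X-chromosomal pedigree kinship coefficient
#'
#' Kinship on the X with male hemizygosity: a male carries a single X
#' received from his mother, so for male `a`, `phiX(a, b) = phiX(mother_a,
#' b)` and his self-kinship is 1; a female recurses through both parents
#' with self-kinship `(1 + fX) / 2`. Under this convention mother-son and
#' father-daughter kinship are both 0.5 and father-son kinship is 0, which
#' is what makes paternal and maternal relationships of equal autosomal
#' degree distinguishable on the X.
#'
#' @inheritParams kinship_auto
#' @return X kinship coefficient in `[0, 1]`.
#' @export
kinship_x <- function(ped, a, b) {
  stopifnot(inherits(ped, "pk_pedigree"))
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste0(i, ":", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      if (ped$sex[i] == "M") 1
      else {
        fa <- ped$father[i]
        if (is.na(fa)) 0.5
        else 0.5 * (1 + phi(ped_index(ped, fa), ped_index(ped, ped$mother[i])))
      }
    } else {
      d <- if (ped$depth[i] >= ped$depth[j]) i else j
      o <- if (d == i) j else i
      if (is.na(ped$father[d])) 0
      else if (ped$sex[d] == "M") phi(ped_index(ped, ped$mother[d]), o)
      else 0.5 * (phi(ped_index(ped, ped$father[d]), o) +
                    phi(ped_index(ped, ped$mother[d]), o))
    }
    memo[[key]] <- val
    val
  }
  phi(ped_index(ped, a), ped_index(ped, b))
}

#' Gene-dropping Monte-Carlo kinship oracle
#'
#' Estimates autosomal and X kinship for a pair by repeated single-locus
#' Mendelian transmission from uniquely labelled founder alleles: in each
#' replicate one allele is drawn at random from each individual (hemizygous
#' males contribute their single X) and the kinship coefficient is the
#' proportion of replicates in which the two draws are identical by
#' descent. Serves as an independent check on the analytic recursions.
#'
#' @param ped A [pedigree()].
#' @param a,b Member ids.
#' @param n_reps Number of replicates (default 1e5).
#' @param seed Optional integer seed.
#' @return Tibble with `theta_auto`, `theta_x` and their binomial
#'   Monte-Carlo standard errors.
#' @export
gene_drop_oracle <- function(ped, a, b, n_reps = 1e5, seed = NULL) {
  stopifnot(inherits(ped, "pk_pedigree"))
  n <- nrow(ped)
  ia <- ped_index(ped, a); ib <- ped_index(ped, b)
  ord <- order(ped$depth)
  with_seed(seed, {
    # autosomes: two alleles per member, columns = replicates
    A1 <- matrix(0L, n, n_reps); A2 <- matrix(0L, n, n_reps)
    # X: females two alleles, males one (stored in X1)
    X1 <- matrix(0L, n, n_reps); X2 <- matrix(0L, n, n_reps)
    next_allele <- 1L
    for (i in ord) {
      fa <- match(ped$father[i], ped$id)
      if (is.na(fa)) {
        A1[i, ] <- next_allele; A2[i, ] <- next_allele + 1L
        if (ped$sex[i] == "M") {
          X1[i, ] <- next_allele + 2L
          next_allele <- next_allele + 3L
        } else {
          X1[i, ] <- next_allele + 2L; X2[i, ] <- next_allele + 3L
          next_allele <- next_allele + 4L
        }
      } else {
        mo <- match(ped$mother[i], ped$id)
        pickf <- runif(n_reps) < 0.5
        pickm <- runif(n_reps) < 0.5
        A1[i, ] <- ifelse(pickf, A1[fa, ], A2[fa, ])
        A2[i, ] <- ifelse(pickm, A1[mo, ], A2[mo, ])
        xm <- ifelse(runif(n_reps) < 0.5, X1[mo, ], X2[mo, ])
        if (ped$sex[i] == "M") {
          X1[i, ] <- xm
        } else {
          X1[i, ] <- X1[fa, ]  # father's single X goes to daughters
          X2[i, ] <- xm
        }
      }
    }
    draw2 <- function(v1, v2, is_male) {
      if (is_male) return(v1)
      ifelse(runif(n_reps) < 0.5, v1, v2)
    }
    da <- ifelse(runif(n_reps) < 0.5, A1[ia, ], A2[ia, ])
    db <- ifelse(runif(n_reps) < 0.5, A1[ib, ], A2[ib, ])
    hit_a <- mean(da == db)
    dxa <- draw2(X1[ia, ], X2[ia, ], ped$sex[ia] == "M")
    dxb <- draw2(X1[ib, ], X2[ib, ], ped$sex[ib] == "M")
    hit_x <- mean(dxa == dxb)
    tibble(
      theta_auto = hit_a,
      se_auto = sqrt(hit_a * (1 - hit_a) / n_reps),
      theta_x = hit_x,
      se_x = sqrt(hit_x * (1 - hit_x) / n_reps),
      n_reps = n_reps
    )
  })
}
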