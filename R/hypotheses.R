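# Relationship-hypothesis enumeration for an observed pair.
#
# Hypotheses are built as explicit sexed pedigrees containing the proband
# ("P") and the relative ("R") plus the minimal set of linking members, so
# expected autosomal and X kinship coefficients come straight from the
# analytic recursions. Lineage-sex variants (paternal vs maternal at every
# link) are enumerated because they share the autosomal coefficient but
# differ on the X - the signal that distinguishes, e.g., a paternal from a
# maternal great-aunt.

parent_word <- function(s) ifelse(s == "M", "father", "mother")
child_word <- function(s) ifelse(s == "M", "son", "daughter")

rel_word <- function(class, sex) {
  switch(class,
    parent = ifelse(sex == "M", "father", "mother"),
    offspring = child_word(sex),
    sibling = ifelse(sex == "M", "brother", "sister"),
    half_sibling = ifelse(sex == "M", "half-brother", "half-sister"),
    grandparent = ifelse(sex == "M", "grandfather", "grandmother"),
    grandchild = ifelse(sex == "M", "grandson", "granddaughter"),
    avuncular = ifelse(sex == "M", "uncle", "aunt"),
    nibling = ifelse(sex == "M", "nephew", "niece"),
    great_grandparent = ifelse(sex == "M", "great-grandfather", "great-grandmother"),
    great_grandchild = ifelse(sex == "M", "great-grandson", "great-granddaughter"),
    great_avuncular = ifelse(sex == "M", "great-uncle", "great-aunt"),
    great_nibling = ifelse(sex == "M", "great-nephew", "great-niece"),
    half_avuncular = ifelse(sex == "M", "half-uncle", "half-aunt"),
    half_nibling = ifelse(sex == "M", "half-nephew", "half-niece"),
    first_cousin = "first cousin"
  )
}

opp <- function(s) ifelse(s == "M", "F", "M")

mk_ped <- function(...) {
  rows <- list(...)
  pedigree(bind_rows(lapply(rows, function(r) {
    tibble(id = r[[1]], sex = r[[2]],
           father = if (length(r) > 2) r[[3]] else NA_character_,
           mother = if (length(r) > 2) r[[4]] else NA_character_)
  })))
}

mem <- function(id, sex, father = NA_character_, mother = NA_character_) {
  list(id, sex, father, mother)
}

# child row with parents given in arbitrary order
chd <- function(id, sex, p1, p1_sex, p2) {
  if (p1_sex == "M") mem(id, sex, p1, p2) else mem(id, sex, p2, p1)
}

# Builders return list(name, ped). `jr` is the junior member id, `sr` the
# senior/lateral one; sexes are looked up from the pair.
build_hypothesis <- function(class, jr, jr_sex, sr, sr_sex, s1 = NULL, s2 = NULL) {
  sp <- function(i) paste0("sp", i)  # founder spouses
  ped <- switch(class,
    parent = mk_ped(mem(sr, sr_sex), mem(sp(1), opp(sr_sex)),
                    chd(jr, jr_sex, sr, sr_sex, sp(1))),
    sibling = mk_ped(mem("gf", "M"), mem("gm", "F"),
                     mem(jr, jr_sex, "gf", "gm"), mem(sr, sr_sex, "gf", "gm")),
    half_sibling = mk_ped(mem("sh", s1), mem(sp(1), opp(s1)), mem(sp(2), opp(s1)),
                          chd(jr, jr_sex, "sh", s1, sp(1)),
                          chd(sr, sr_sex, "sh", s1, sp(2))),
    grandparent = mk_ped(mem(sr, sr_sex), mem(sp(1), opp(sr_sex)),
                         chd("l1", s1, sr, sr_sex, sp(1)),
                         mem(sp(2), opp(s1)),
                         chd(jr, jr_sex, "l1", s1, sp(2))),
    avuncular = mk_ped(mem("gf", "M"), mem("gm", "F"),
                       mem("l1", s1, "gf", "gm"), mem(sr, sr_sex, "gf", "gm"),
                       mem(sp(1), opp(s1)),
                       chd(jr, jr_sex, "l1", s1, sp(1))),
    great_grandparent = mk_ped(mem(sr, sr_sex), mem(sp(1), opp(sr_sex)),
                               chd("g1", s2, sr, sr_sex, sp(1)),
                               mem(sp(2), opp(s2)),
                               chd("l1", s1, "g1", s2, sp(2)),
                               mem(sp(3), opp(s1)),
                               chd(jr, jr_sex, "l1", s1, sp(3))),
    great_avuncular = mk_ped(mem("ggf", "M"), mem("ggm", "F"),
                             mem("g1", s2, "ggf", "ggm"),
                             mem(sr, sr_sex, "ggf", "ggm"),
                             mem(sp(1), opp(s2)),
                             chd("l1", s1, "g1", s2, sp(1)),
                             mem(sp(2), opp(s1)),
                             chd(jr, jr_sex, "l1", s1, sp(2))),
    half_avuncular = mk_ped(mem("sh", s2), mem(sp(1), opp(s2)), mem(sp(2), opp(s2)),
                            chd("l1", s1, "sh", s2, sp(1)),
                            chd(sr, sr_sex, "sh", s2, sp(2)),
                            mem(sp(3), opp(s1)),
                            chd(jr, jr_sex, "l1", s1, sp(3))),
    first_cousin = mk_ped(mem("gf", "M"), mem("gm", "F"),
                          mem("l1", s1, "gf", "gm"), mem("l2", s2, "gf", "gm"),
                          mem(sp(1), opp(s1)), mem(sp(2), opp(s2)),
                          chd(jr, jr_sex, "l1", s1, sp(1)),
                          chd(sr, sr_sex, "l2", s2, sp(2)))
  )
  ped
}

#' Enumerate candidate relationships for an observed pair
#'
#' Generates all sex-resolved pedigree hypotheses of the requested degree
#' for a pair with known sexes: degree 1 (parent-offspring, full siblings),
#' degree 2 (half-siblings, grandparent-grandchild, avuncular), degree 3
#' (great-grandparents, great-aunts/uncles, half-aunts/uncles, first
#' cousins), each with every paternal/maternal variant at the linking
#' steps. With `proband_nonancestral = TRUE` (an individual who died before
#' reproductive age) every hypothesis that connects the pair through the
#' proband's descendants or places the proband upstream is pruned, leaving
#' only relationships reached through the proband's parents.
#'
#' @param proband_sex,relative_sex `"F"` or `"M"` (also accepts
#'   `"female"`/`"male"`).
#' @param degree Relationship degree, 1, 2 or 3.
#' @param proband_nonancestral Prune hypotheses with the proband upstream.
#' @return Tibble with `name`, `class`, expected `theta_auto` and `theta_x`,
#'   and the hypothesis pedigree in list-column `ped` (proband `"P"`,
#'   relative `"R"`).
#' @export
enumerate_hypotheses <- function(proband_sex, relative_sex, degree,
                                 proband_nonancestral = FALSE) {
  px <- dplyr::recode(tolower(proband_sex), female = "F", male = "M", f = "F", m = "M")
  rx <- dplyr::recode(tolower(relative_sex), female = "F", male = "M", f = "F", m = "M")
  if (!degree %in% 1:3) stop_pk("degree must be 1, 2 or 3")
  sexes <- c("M", "F")
  out <- list()
  add <- function(name, class, ped) {
    out[[length(out) + 1]] <<- tibble(name = name, class = class, ped = list(ped))
  }

  if (degree == 1) {
    add(rel_word("parent", rx), "parent_offspring",
        build_hypothesis("parent", "P", px, "R", rx))
    if (!proband_nonancestral) {
      add(rel_word("offspring", rx), "parent_offspring",
          build_hypothesis("parent", "R", rx, "P", px))
    }
    add(paste("full", rel_word("sibling", rx)), "full_sibling",
        build_hypothesis("sibling", "P", px, "R", rx))
  } else if (degree == 2) {
    for (s1 in sexes) {
      add(paste0(rel_word("half_sibling", rx), " via shared ", parent_word(s1)),
          "half_sibling", build_hypothesis("half_sibling", "P", px, "R", rx, s1 = s1))
      add(paste0(rel_word("grandparent", rx), " via ", parent_word(s1)),
          "grandparent", build_hypothesis("grandparent", "P", px, "R", rx, s1 = s1))
      add(paste0(rel_word("avuncular", rx), " via ", parent_word(s1)),
          "avuncular", build_hypothesis("avuncular", "P", px, "R", rx, s1 = s1))
      if (!proband_nonancestral) {
        add(paste0(rel_word("grandchild", rx), " via ", child_word(s1)),
            "grandparent", build_hypothesis("grandparent", "R", rx, "P", px, s1 = s1))
        add(paste0(rel_word("nibling", rx), " via proband's ",
                   rel_word("sibling", s1)),
            "avuncular", build_hypothesis("avuncular", "R", rx, "P", px, s1 = s1))
      }
    }
  } else {
    for (s1 in sexes) for (s2 in sexes) {
      add(paste0(rel_word("great_grandparent", rx), " via ", parent_word(s1),
                 "'s ", parent_word(s2)),
          "great_grandparent",
          build_hypothesis("great_grandparent", "P", px, "R", rx, s1 = s1, s2 = s2))
      add(paste0(rel_word("great_avuncular", rx), " via ", parent_word(s1),
                 "'s ", parent_word(s2)),
          "great_avuncular",
          build_hypothesis("great_avuncular", "P", px, "R", rx, s1 = s1, s2 = s2))
      add(paste0(rel_word("half_avuncular", rx), " via ", parent_word(s1),
                 " (shared ", ifelse(s2 == "M", "grandfather", "grandmother"), ")"),
          "half_avuncular",
          build_hypothesis("half_avuncular", "P", px, "R", rx, s1 = s1, s2 = s2))
      add(paste0(rel_word("first_cousin", rx), " via ", parent_word(s1),
                 " and relative's ", parent_word(s2)),
          "first_cousin",
          build_hypothesis("first_cousin", "P", px, "R", rx, s1 = s1, s2 = s2))
      if (!proband_nonancestral) {
        add(paste0(rel_word("great_grandchild", rx), " via ", child_word(s1),
                   "'s ", child_word(s2)),
            "great_grandparent",
            build_hypothesis("great_grandparent", "R", rx, "P", px, s1 = s1, s2 = s2))
        add(paste0(rel_word("great_nibling", rx), " via proband's ",
                   rel_word("sibling", s2), "'s ", child_word(s1)),
            "great_avuncular",
            build_hypothesis("great_avuncular", "R", rx, "P", px, s1 = s1, s2 = s2))
        add(paste0(rel_word("half_nibling", rx), " via proband's ",
                   rel_word("half_sibling", s1), " (shared ",
                   ifelse(s2 == "M", "father", "mother"), ")"),
            "half_avuncular",
            build_hypothesis("half_avuncular", "R", rx, "P", px, s1 = s1, s2 = s2))
      }
    }
  }
  hyps <- bind_rows(out)
  hyps$theta_auto <- vapply(hyps$ped, kinship_auto, numeric(1), a = "P", b = "R")
  hyps$theta_x <- vapply(hyps$ped, kinship_x, numeric(1), a = "P", b = "R")
  hyps$degree <- degree
  hyps[, c("name", "class", "degree", "theta_auto", "theta_x", "ped")]
}

#' Rank relationship hypotheses against observed kinship
#'
#' Scores every hypothesis by the squared standardized distance between its
#' expected and the observed autosomal and X kinship coefficients,
#' `((ta - ta_obs)/se_a)^2 + ((tx - tx_obs)/se_x)^2`, and sorts ascending
#' (ties broken by name for determinism). The full ranked list is reported
#' rather than a single answer: the top hypothesis is "a possible
#' scenario", not a unique solution.
#'
#' @param hypotheses Output of [enumerate_hypotheses()].
#' @param theta_auto,se_auto Observed autosomal kinship and its SE.
#' @param theta_x,se_x Observed X kinship and its SE.
#' @return The hypothesis tibble with `score` and `rank`, sorted.
#' @export
rank_hypotheses <- function(hypotheses, theta_auto, se_auto, theta_x, se_x) {
  if (se_auto <= 0 || se_x <= 0) stop_pk("SEs must be positive")
  h <- hypotheses
  h$score <- ((h$theta_auto - theta_auto) / se_auto)^2 +
    ((h$theta_x - theta_x) / se_x)^2
  h <- h[order(h$score, h$name), ]
  h$rank <- seq_len(nrow(h))
  h
}
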