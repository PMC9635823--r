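---
title: "Models and methods in paleokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in paleokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleokin)
```

paleokin analyses pseudo-haploid genotypes from low-coverage ancient
genomes: allele-frequency statistics (outgroup f3, D, f4) with block-jackknife
errors, qpAdm-style admixture-weight estimation, READ-style pairwise kinship
with separate autosomal and X estimates, analytic pedigree kinship and
hypothesis ranking, spatial and permutation statistics, and calibrated-date
resampling. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## Pseudo-haploid data

A pseudo-haploid call samples one sequencing read's allele at a SNP and
records it as a homozygous genotype. It is the standard representation for
genomes below ~1x coverage: unbiased at the allele-frequency level but
carrying a single allele per site, so every estimator here treats a
pseudo-haploid individual as contributing one allele copy. In the
`geno_matrix` container calls count copies of `allele1` of the `.snp` record
(diploid 0/1/2; pseudo-haploid and hemizygous-X calls 0/2 only) — stated
explicitly because the EIGENSTRAT text format leaves the reference allele
ambiguous. Positions are 1-based; windows and blocks are half-open
`[start, start + span)`. X SNPs may carry a pseudoautosomal-region mask
(`par` column), excluded from all X analyses; the PAR coordinates are
panel-specific, so the mask is user-supplied.

## f-statistics and the weighted block jackknife

For populations with allele-1 frequencies $p$, the package computes

* outgroup $f_3(O; A, B) = \mathrm{E}[(p_O - p_A)(p_O - p_B)]$, the shared
  drift of $A$ and $B$ relative to an outgroup, with $1 - f_3$ used as a
  genetic distance between individuals;
* $D(W, X; Y, Z) = \sum (p_W - p_X)(p_Y - p_Z) \big/ \sum (p_W + p_X - 2
  p_W p_X)(p_Y + p_Z - 2 p_Y p_Z)$, the normalized ABBA–BABA statistic;
* plain $f_4(A, B; C, D) = \mathrm{E}[(p_A - p_B)(p_C - p_D)]$, the
  building block of admixture modeling.

Each statistic uses every SNP at which the populations involved have data
(per-statistic SNP sets, the "allsnps" convention, robust to low coverage);
a strict-intersection mode is available for comparison in
`build_f4_matrix()`. Standard errors come from a weighted delete-one-block
jackknife over contiguous physical blocks (default 5 Mb, configurable and
recorded in output; the choice matters little beyond the scale of linkage).
Unequal block sizes are handled Busing-style with pseudovalues
$\tau_j = h_j\hat\theta - (h_j - 1)\hat\theta_{-j}$, $h_j = n/m_j$; for the
mean of iid values in singleton blocks this reduces exactly to the classical
standard error, which the tests assert to 1e-10. No small-sample
heterozygosity correction is applied to outgroup f3 by default: with
pseudo-haploid data, comparability across pairs matters more than absolute
scale, and all downstream uses (MDS, regressions, permutation contrasts) are
scale-invariant.

## qpAdm-style admixture weights

The target's frequencies are modelled as $p_T = \sum_i w_i\, p_{S_i}$ with
$\sum_i w_i = 1$. Because f4 is bilinear in frequencies, the residual
statistics $r_j(w) = f_4(T, b; R_j, b) - \sum_i w_i f_4(S_i, b; R_j, b)$
vanish in expectation at the true weights for *any* base population $b$ —
the base cancels under the sum-to-one constraint — so the first reference
population doubles as the base. Weights minimize
$r(w)^\top \Sigma(w)^{-1} r(w)$ where $\Sigma(w)$ is the block-jackknife
covariance of the residual vector; since $\Sigma$ depends on $w$, the
constrained GLS solve is iterated to convergence (a handful of iterations).
The minimized quadratic form is the model chi-square with
$\mathrm{dof} = (n_\mathrm{right} - 1) - (n_\mathrm{sources} - 1)$ —
conventions differ across published implementations, so this artifact's
choice is validated empirically: under a true model the p-value is uniform
(Kolmogorov–Smirnov check in the acceptance suite). Weight standard errors
come from leave-one-block-out refits. A covariance with condition number
above 1e12 is ridge-regularized by adding 1e-10 of its trace to the
diagonal, with a logged warning. A model is *feasible* when $p > 0.05$ and
all weights lie in $[0, 1]$, *marginal* for $0.01 < p \le 0.05$, otherwise
rejected.

## READ-style kinship

For a pair of pseudo-haploid genomes, $P_0$ is the mismatch rate among
jointly called sites, computed in 1-Mb physical windows. The genome-wide
$P_0$ (overlap-weighted across windows) is divided by a baseline
representing an unrelated pair — by default the median $P_0$ over all pairs
in the sample, which assumes most pairs are unrelated; with up to ~20% of
pairs related the median moves the unrelated pairs' kinship by well under
0.02 (a property test). Then $\theta = 1 - P_0^{\mathrm{norm}}$ estimates
the kinship coefficient: expected normalized values are 0.5, 0.75, 0.875,
0.9375 and 1 for identical, first-, second-, third-degree and unrelated
pairs. Classification uses the midpoint cutoffs 0.625 / 0.8125 / 0.90625 /
0.96875 — the third-degree bin extends the published three-bin convention,
because pairs out to third degree are reported with this machinery and the
exact cutoff is not published. Two guards temper the call: the deviation
from 1 must satisfy $|Z| > 2$, with the SE estimated from the variance of
window-level $P_0$ (overlap-weighted SD divided by $\sqrt{n_\mathrm{win}}$,
scaled by the baseline — READ's internal estimator is unpublished, so this
artifact's choice is recorded in the result metadata); and a pair needs more
than 2000 overlapping autosomal SNPs (200 on the X) or it is reported
`insufficient-data`. Pairs classified identical are merged by unioning call
vectors; conflicting co-called sites become missing (conservative,
preserving pseudo-haploid semantics) and the conflict rate is logged. The
Jaccard-coefficient combination $\theta = J_1 + 0.5(J_3 + J_5 + J_7) +
0.25 J_8$ used by genotype-likelihood estimators is provided for
cross-method comparison.

## X-chromosomal kinship and pedigree resolution

The same mismatch pipeline runs on non-PAR X SNPs with the 200-SNP
threshold. On the X, males are hemizygous: a male's single X comes from his
mother, and he passes it to every daughter and no son. The analytic
recursion (`kinship_x()`) therefore sets male self-kinship to 1 — making
mother–son and father–daughter X kinship both 0.5 and father–son 0 —
a convention chosen for internal consistency (conventions differ across
packages) and verified against the gene-dropping Monte-Carlo oracle for
every enumerated hypothesis. The practical payoff is that relationships
with equal autosomal degree separate on the X: a female pair related
through the proband's father's mother shares X kinship 0.1875 at autosomal
third degree (0.0625), while the father's-father-side variant shares none.
`compare_auto_x()` flags such discordance when it exceeds 2 combined SEs,
and `enumerate_hypotheses()` + `rank_hypotheses()` score all sex-resolved
pedigree variants of the four third-degree classes (great-grandparents,
great-aunts/uncles, half-aunts/uncles, first cousins) against the observed
$(\theta_\mathrm{auto}, \theta_X)$ pair by a squared standardized distance.
The full ranked list is reported, not a single answer: the top hypothesis
is a possible scenario, with exact ties broken alphabetically for
determinism. A proband known to have died before reproductive age
constrains the enumeration to relationships reached through its parents
(`proband_nonancestral = TRUE`).

## Spatial and permutation statistics

Pairwise $(1 - f_3)$ dissimilarities feed three analyses.

*Classical MDS* wraps `stats::cmdscale` (Torgerson double-centering) with a
deterministic sign convention (largest-magnitude coordinate per axis made
positive). Pairs below 2000 overlapping SNPs are masked; masked entries are
imputed with the mean off-diagonal dissimilarity by default (warned), or
the most-masked individuals can be dropped until the matrix is complete —
imputation keeps every individual but shrinks masked pairs toward the
centre, so heavily masked datasets should prefer `impute = "drop"`.

*Isolation by distance* regresses genetic on geodesic distance (haversine
on a sphere of mean radius 6371.0088 km; the ellipsoidal alternative
differs by < 0.5%). Pairs from the same site, more than 1000 years apart,
or below 2000 overlapping SNPs are excluded. Pairs sharing an individual
are not independent, so alongside the naive `lm` p-value the package offers
`residuals_by_group()`, a label-permutation test of group median residuals
with BH adjustment across groups.

*Permutation tests* (within-site diversity contrasts; the coburial test of
whether individuals interred in the same building are genetically closer
after excluding close kin) permute **individuals'** labels, preserving
group sizes, never pair labels — shuffling pairs would break the dependence
among pairs sharing an individual and invalidate the null. P-values carry
the add-one correction, so $p \ge 1/(n_\mathrm{perm} + 1)$ always; the
coburial test is one-sided (within-building pairs closer) and its effect
size is the raw difference of mean $(1 - f_3)$ between between- and
within-building pairs. Calibration is checked empirically: with labels
assigned at random the rejection rate at $\alpha = 0.05$ stays within
binomial error of 0.05 over 500 label draws on one simulated dataset —
a conditional (on genotypes) validity check, which is exactly the guarantee
a permutation test gives.

## Dates

Calibrated age densities are consumed, never produced (calibration is
upstream). For synthetic data they are truncated-Gaussian grids on integer
years cal BCE. Temporal overlap of a pair is judged by resampling ages
10,000 times and asking whether the 95% interval of the difference contains
0 — the criterion is implied rather than stated in common practice, so it
is labelled in the output. Summed probability distributions are stacked per
group in 100-year bins aligned to multiples of the width; total mass equals
the number of individuals, which the tests assert exactly.

## The synthetic world

The generator produces the statistical structure the analyses assume, with
full truth tables, so every stage is testable without downloads.

* **Population structure.** Ancestral frequencies are uniform on
  (0.05, 0.95) — every SNP polymorphic, mirroring a common-variant
  (MAF > 10%) panel. Populations drift via the Balding–Nichols
  distribution, Beta with mean $p$ and variance $F p(1-p)$ (unbiased, the
  tests check the closed form by Monte Carlo). Side branches drift from a
  parent population; admixed populations are *exact* frequency mixtures,
  which is what makes weight recovery well-posed. The default world has an
  outgroup ($F = 0.5$), three sources on an east–west cline
  ($F = 0.06$–$0.10$), one drifted reference branch per source (the qpAdm
  right set), and a target mixed 0.48 / 0.33 / 0.19 — a three-way structure
  of the kind the method is built for.
* **Pedigrees.** Genotypes descend from founders by per-SNP Mendelian gene
  dropping, with the X transmitted hemizygously. SNPs are unlinked (no
  recombination map): every statistic here is LD-agnostic, and physical
  positions are still assigned (uniform over human-like chromosome lengths)
  so that 1-Mb windows and 5-Mb blocks are meaningful. The default planted
  family covers identical (duplicated genome, independently observed),
  first-, second- and third-degree pairs including the paternal great-aunt
  configuration whose X signature the pedigree machinery must resolve.
* **Cline worlds.** `sim_cline_config()` builds a serial-founder chain
  along a longitudinal transect: genetic divergence accumulates with the
  number of chain steps, giving the distance-decay pattern the IBD
  regression should recover. One subtlety is worth stating: outgroup f3
  between two individuals measures their *shared* drift path, so drift
  strictly private to one terminal branch cannot move cross-site
  dissimilarities at all. A "strongly differentiated" population is
  therefore modelled as an early-diverging long branch — it attaches to
  the chain several nodes upstream of its geographic position — which
  shortens its shared path with every neighbour and is exactly the signal
  the regression residuals respond to. Private terminal drift does,
  however, drive the within-site diversity contrast, where both members of
  a pair share it.
* **Observation.** Diploid truth is pseudo-haploidized: one allele per
  site, flipped with probability 0.005 (a symmetric error; no
  damage-profile simulation — damage handling is out of scope), each site
  retained with probability 0.7 per individual.
* **Metadata.** Sites with coordinates, three coburial buildings at the
  target site, and per-individual truncated-Gaussian date distributions.

What passing tests on this world do **not** show: robustness to linkage
(blocks exist, but LD is not simulated), to reference bias or damage, to
strong inbreeding (founders are outbred), or to panel ascertainment beyond
the MAF filter. Those effects live upstream of this package's scope.

## Problem sizes and numerical choices

The validation suite uses sizes chosen to give each check adequate power on
one CPU in minutes: 1k-SNP fixtures for exact-oracle equality (1e-12);
200 replicates at 4k SNPs for D null calibration; 3 seeds x 50 replicates
each of two- and three-way models at 50k SNPs for weight recovery (every
weight within 3 jackknife SEs in >= 94% of replicates) plus 100 runs for
misspecification power; five replicate worlds at ~10k overlapping SNPs per
pair for kinship classification; 1e5 gene-dropping replicates per pedigree
hypothesis; 500 label draws for permutation calibration. Degenerate inputs
are errors, not silent results: a single jackknife block, a zero baseline
P0, zero variance in geographic distance, an all-in-one-building test, or a
pedigree member with exactly one parent all abort with a message naming the
problem. Seeds propagate through a single integer: every randomized
function takes `seed` and restores the caller's RNG state, and
`simulate_dataset()` is byte-reproducible for a fixed seed.

## Known limitations

* The qpAdm dof and SE conventions are this package's own (validated by
  calibration, not by matching another implementation's output on real
  data); absolute p-values may differ from other tools even on identical
  input.
* The window-based kinship SE is an approximation whose accuracy degrades
  below a few hundred windows; the X estimates for low-coverage pairs are
  correspondingly noisy, which is why the 200-SNP floor and the |Z| rule
  are enforced.
* `ibd_regression`'s naive p-value ignores pair non-independence; use the
  permutation machinery when it matters.
* The identical-pair merge assumes the pair really is one genome observed
  twice; for genuine monozygotic twins buried separately the merge is still
  statistically sound but archaeologically misleading — the merge log and
  conflict rate are reported so the call can be audited.
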