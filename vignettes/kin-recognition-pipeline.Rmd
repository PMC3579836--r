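---
title: "From STR genotypes to kin-recognition experiments: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From STR genotypes to kin-recognition experiments: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`kinfaces` implements the computational chain behind visual kin-recognition
experiments in pedigreed primate colonies: diagnosing an STR genotype
database, assigning parentage by exclusion plus likelihood, computing
pedigree relatedness with explicit handling of unresolved paternity,
constructing constraint-satisfying forced-choice stimulus triads, and
analysing 8-point similarity ratings with crossed-random-effects Gaussian
mixed models. A synthetic-data generator stands in for the colony and its
human raters, so every stage can be exercised and validated end to end
against known truth. This vignette records the models, the tunable
parameters, and the design decisions that were genuinely open.

## The synthetic colony

`sim_config()` fixes the study conditions. The defaults emulate a
free-ranging island colony of roughly 850 macaques: 160 founders plus 17
years of 40 births (840 individuals), polygynous mating, and a genotype
database of 21 STR loci with about 7 alleles each.

* **Reproductive skew.** Each year every male draws a gamma(`male_skew`)
  weight (a Dirichlet draw over the eligible males, `male_skew = 0.5` by
  default); sires are sampled by these weights for all of that year's
  conceptions. Drawing the weights *per year* rather than per birth is what
  produces overdispersion in male reproductive output relative to a uniform
  multinomial — the property the tests check by simulation against that
  null.
* **Inbreeding avoidance.** A proposed mating with pedigree relatedness at
  or above `inbreeding_avoidance_r` (default 0.25) is rejected and the sire
  redrawn. The threshold form is deliberately transparent: the empirical
  avoidance pattern in the source population is unpublished, so a single
  configurable cutoff is the most defensible stand-in.
* **Male reproductive age.** No canonical value is published for age at
  first siring in this setting; the default of 6 years is realistic for
  free-ranging rhesus males and is exposed as `reproductive_age_male`.
  Females enter the dam pool at 4 years, the conventional age of sexual
  maturity.
* **Genotypes.** Founder allele frequencies are Dirichlet draws
  (`allele_freq_concentration = 1`); inheritance is fair Mendelian
  transmission. Typing error replaces each recorded allele, independently
  with probability `typing_error_rate` (default 1%), by a uniformly random
  *different* allele — the simplest process that reproduces aggregate
  mother-offspring mismatch rates of about 10% at colony scale, matching
  the order reported for real STR databases of this kind.
* **Missingness.** Real STR databases are not "missing at random across
  loci": most animals are typed on a core panel, supplementary loci are
  typed sporadically, and a minority of animals are sparsely sampled. The
  generator therefore types a 12-locus core at 98% and spreads the
  remainder so the expected typed-locus count matches `mean_typed_loci`
  (default 14.6), with 15% of individuals at half rates. This structure
  matters: with independent random missingness the three-way overlap of a
  mother-father-offspring trio would almost never reach the 12 common loci
  that testability requires, which is not how such databases behave.

What the generator does *not* emulate: spatial group structure, male
migration between named groups, age-dependent fertility, and any linkage
or mutation at the markers. Passing tests therefore demonstrate that the
*machinery* is correct under idealised Mendelian sampling, not that the
pipeline is robust to population structure misspecification.

## Marker diagnostics

`locus_summary()` reports observed heterozygosity, expected heterozygosity
with Nei's small-sample correction (`He = (2n/(2n-1))(1 - sum p_i^2)`;
disable with `unbiased = FALSE`), and polymorphic information content
(`PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`). Hardy-Weinberg
equilibrium is tested by a seedable Monte-Carlo exact test: alleles are
re-paired at random and the conditional probability of each table is
compared with the observed one. With ~7 alleles and sparse genotype
classes the asymptotic chi-square is unreliable, which is why the exact
test is the default (10,000 permutations; the tests verify both agreement
with chi-square where counts are large and uniformity of the p-value under
the null). Null alleles are screened as a heterozygote-deficit z-score
below -1.96; no specific estimator is canonical here, and the flag is
advisory.

## Parentage

Candidate sires for an infant are the males of reproductive age whose
census presence interval covers the date 200 days before the birth — a
conservative window covering conception plus gestation.

Assignment combines exclusion and likelihood:

1. **Testability, not guilt.** A mother-father-offspring trio must share at
   least 12 typed loci, a father-offspring duo at least 15. Candidates
   below the threshold are *untestable*, never excluded.
2. **Strict exclusion.** A unique zero-mismatch candidate whose testable
   rivals all carry two or more Mendelian mismatches is accepted outright.
3. **Likelihood confirmation.** If some rival is excluded at only one
   locus, the zero-mismatch candidate must also have the top LOD score and
   a lead (delta) over the runner-up of at least the simulated 95% critical
   value.

The LOD is the standard trio/duo paternity likelihood ratio with a
genotyping-error mixture: each observed genotype is treated as correct with
probability 1 − e and as an uninformative random population genotype with
probability e. The error parameter defaults to the observed
mother-offspring mismatch rate, and maternal-mismatch loci fall back to duo
logic rather than aborting the trio (a low rate of such mismatches is
expected and tolerated in real databases). Incompatible candidates at
e = 0 receive a finite large-negative sentinel instead of −Inf so sorting
stays stable. `confidence_critical_delta()` reproduces the usual
simulation: offspring are generated from random true sires under the
specified sampling and typing conditions, and the critical delta is the
smallest LOD gap at which the requested proportion of assignments is
correct; when the level is met without any gating the critical value is 0.

On the default synthetic colony (1% per-allele error, ~180 candidates per
infant), the cohort driver solves roughly a third of paternities with
better than 99% accuracy against the simulated truth; precision rather
than yield is the design goal, mirroring the conservative two-stage rule.

## Kinship and unresolved paternity

`kinship_coefficient()` is the textbook recursion (f of an individual with
itself is (1 + f(dam, sire))/2; otherwise average over the later-born
member's parents), memoised, with unknown parents treated as unique
unrelated founders — so r = 2f is a lower bound under pedigree
incompleteness, and the package says so rather than guessing.
`gene_drop_relatedness()` is the independent Monte-Carlo validator: unique
founder alleles are dropped down the pedigree and identity-by-descent is
averaged over the four allele comparisons. The tests require agreement on
dozens of random pedigrees within Monte-Carlo error.

Reported r values round half-up (`round_half_up()`): 0.0625 prints as
0.063, matching field convention. Note the deliberate strictness ordering:
a pair sharing exactly one grandparent has r = 0.0625, *below* the 0.063
screening threshold, yet `unrelated_two_generations()` still rejects it,
because the predicate intersects ancestor sets (self, parents,
grandparents) rather than thresholding r.

When a sire or grandsire is unknown, unknown ancestry is never silently
treated as "unrelated". Given candidate-sire sets (males present at
conception and not excluded genetically), `expected_relatedness()` grafts
each candidate in turn, weights candidates uniformly after zeroing those
whose relatedness with the dam reaches the inbreeding-avoidance threshold
(default 0.25, configurable for the same reason as in the simulator), and
averages r over the product of choices when both members are unresolved.
If every candidate is zeroed the weights fall back to uniform with a
warning rather than failing silently.

## Stimulus design

Kin-discrimination (KD) triads show a parent target with its offspring
(r ≥ 0.5 by pedigree) and a decoy of the same sex as the offspring, within
two whole years of age at photo date, two-generation-unrelated to both
target and match, with match and decoy images in the same lighting class;
all animals are at least 4 years old. Eight triads in each of four
conditions (mother-daughter, mother-son, father-daughter, father-son).
Exactly five sires serve as targets twice — once per father condition —
because high-quality images of assigned sires are scarce; every other
animal appears once, so 32 triads contain 91 distinct animals.
Individual-discrimination (ID) triads pair a frontal target with a
three-quarter view of the same animal against a matched decoy facing the
same way: six male and six female triads, three facing left and three
facing right within each sex.

The builder is a greedy constraint search with seeded restarts; ties in
decoy selection break by smallest age gap then lexicographic id, making
designs reproducible. Infeasible inventories fail loudly, naming the
condition that could not be filled.

"Interleaved evenly" is formalised as a four-quarter quota: each quarter of
the 44-trial session holds two triads of every KD condition and three ID
trials, with ID conditions rotated so each appears three times, and order
shuffled within quarter. The side of the correct image is counterbalanced
exactly 22 left / 22 right — exact balance was chosen over independent
coin flips because "randomized left-right" is ambiguous and exactness is
testable. The session's break marker sits at its midpoint (after trial 22
of 44). `validate_design()` re-checks every invariant independently of the
builders and is run on all generated designs in the tests.

## Rater responses and the analysis chain

Scores live on the 8-point grid −3.5 … +3.5 (no zero); the sign is
positive when the correct image is chosen. The simulator builds a latent
Gaussian score — fixed effects of kin line, triad type, experience,
z-scored trial position and their configured interactions, plus crossed
random intercepts for participant, triad, target image, left image and
right image, plus residual noise — and discretises to the nearest grid
point, clamping at ±3.5. Exact midpoints, including a latent value of 0,
resolve toward the positive side; the scale has no zero point, so some
deterministic tie rule is required, and a fixed one keeps simulations
reproducible. Default fixed effects mirror the structure of a completed
kin-discrimination analysis (intercept 0.17, paternal line +0.47, same-sex
+0.34, experience +0.33, position +0.25, line-by-experience −0.30,
position-by-experience −0.19, ID intercept 2.14); random-effect scales
(participant 0.3, triad 0.4, images 0.2, residual 1.5 score units) were
chosen once so that per-participant mean scores spread by roughly 0.3 —
the order observed in such experiments — and are not revisited. One known
artefact: because a single participant intercept spans both tasks, the
generator induces a positive correlation between a rater's ID and KD means
that need not exist in real data.

Models are fitted by maximum likelihood with `lme4::lmer` (ML rather than
REML, so likelihood-ratio tests between fixed-effect specifications are
valid); the crossed random-intercept structure is exactly the five-factor
design above. The package's own contribution is the surrounding machinery:
the staged reduction, the LRT bookkeeping, and the intervals. Where a
published analysis of this design reported MCMC-based HPD intervals and
p-values, this package substitutes seeded parametric-bootstrap percentile
intervals (≥1,000 simulate-refit draws) and LRT p-values — the same
estimands with different uncertainty machinery; this is the one intentional
methodological substitution. Wald intervals are the default in
`fit_lmm()` because coverage checks across many replicates do not need
1,000 refits each; the bootstrap is switched on (`ci = "boot"`) for
headline intercept estimates.

`reduce_model()` implements the staged procedure: test the random
intercept-slope correlation, then the random slope, by LRT; establish the
full model against a control-only null; drop nonsignificant interactions
from the highest order down, then nonsignificant control main effects,
respecting marginality; retain "trend" terms at p < 0.10 (no cutoff is
canonical for trend retention — 0.10 is fixed here and documented); never
drop the first-order terms of primary interest. Estimates in the trace
come from the last model containing each term. Finally, all nonsignificant
fixed effects are excluded and the intercept — the quantity of interest,
since a positive intercept means the related image is preferred — is
reported with its bootstrap interval; when experience is significant (as a
main effect or inside a retained interaction) the intercept model is
fitted separately per experience group, retaining within each group
whatever remaining terms stay significant there.

Numerical conventions: `lmer` singular fits (zero variance components) are
accepted as boundary estimates; convergence messages flag a fit as
non-converged rather than erroring; the z-transform of trial position is
recomputed within each analysis subset; chi-square statistics are clamped
at zero when a reduced fit is numerically better; identical model
specifications compare as chi-square 0 with p = 1.

## Problem sizes used in validation

The reference validation runs use the default 840-individual colony, 500
simulated paternity cases with 50 candidates each, 50 random pedigrees for
gene-dropping agreement, 1,000 null participants for t-test calibration,
and 20 replicate experiments of 200 participants for interval coverage and
end-to-end sign recovery. These sizes give stable Monte-Carlo behaviour at
desk scale; all are parameters, not limits.

## Known limitations

* Pedigree r is a lower bound under missing parentage; the expected-r
  machinery mitigates but cannot remove this.
* The likelihood error model treats a mistyped genotype as wholly
  uninformative; allele-level error models would be sharper but require
  assumptions the aggregate mismatch rate cannot identify.
* The critical-delta simulation assumes unrelated rival candidates;
  relatives among rivals compress true deltas.
* Bootstrap p-values for intercepts are resolution-limited by the number
  of draws; values reported as 0 mean "below 1/nboot".
* The reduction procedure inherits the usual caveats of stepwise testing;
  it is implemented because it is the analysis convention for this design,
  not as a recommendation for de novo analyses.
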