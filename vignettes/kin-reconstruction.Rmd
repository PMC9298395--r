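---
title: "Reconstructing kinship and social structure in cooperative cichlid groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing kinship and social structure in cooperative cichlid groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinrecon)
```

## The problem

Cooperatively breeding lamprologine cichlids live in multi-layered
societies: a breeder male defends a territory ("group" or harem)
containing one to several breeder females, each with her own subterritory
and subordinate helpers ("subgroup"). Whether helping pays through kin
selection or through direct benefits (shared reproduction, territory
inheritance, tolerated membership) hinges on the relatedness structure of
these layers — which must be reconstructed from co-dominant marker
genotypes, body sizes, and group membership, because pedigrees are not
observable in the field.

`kinrecon` implements that reconstruction as a reusable, testable
pipeline, plus a forward simulator whose truth tables measure how well
each inferential step recovers a known social history.

## Growth and age

Individual age is never observed; the pipeline uses the standard
size-to-age transform for these fish. Daily growth declines log-linearly
with standard length (SL):

$$ g(s) = \alpha + \beta \ln s \quad \text{(mm/day)},
   \qquad \alpha = 0.38,\ \beta = -0.087 $$

so age is the quadrature $t(s) = \int_{s_0}^{s} \mathrm{d}u / g(u)$, with
asymptotic size $s_\infty = e^{-\alpha/\beta} \approx 78.9$ mm. The
original analysis used a parametric (Blumberg) growth curve fitted by an
earlier study; we instead integrate the fitted *rate* regression
directly, which uses exactly the published coefficients and avoids
importing an unpublished parameterisation. Only age differences matter
downstream, so the anchor `s0 = 6.5` mm (the smallest genotyped fish)
merely fixes the origin. Numerical choices: adaptive quadrature at
relative tolerance 1e-8, inversion by root bracketing to 1e-10; a
fixed-step Simpson oracle in the test suite agrees to < 1e-6 days.

```{r}
gm <- growth_model()
c(s_inf = gm$s_inf, age_at_31mm = age_from_size(31, gm))
```

The ~200 d age equivalent of 31 mm is why the parentage stage's "adult at
spawning" rule and the published "age gap of at least 210 d" rule select
nearly the same candidate sets.

## Relatedness and its reference frequencies

Pairwise relatedness is the symmetric (ratio-of-sums) Queller–Goodnight
estimator; expectations are 0.5 / 0.5 / 0.25 / 0 for parent–offspring,
full sibs, half sibs, unrelated pairs, verified by Monte-Carlo in the
acceptance suite. Loci missing in either member are skipped; a dyad whose
denominator vanishes (all loci uninformative) is an explicit error, not a
number.

Allele frequencies are the reference for every estimate and likelihood.
Because field samples are full of relatives, naive counting
over-represents family alleles. The study used a relatedness-corrected
frequency estimate from a legacy tool whose algorithm is not reprinted;
we provide a documented stand-in — iteratively down-weight each
individual by $1/(1 + \bar r_i)$ (its mean relatedness to all others) and
re-estimate until frequencies change < 1e-6 (max 20 passes) — plus an
external allele-frequency-block input for bit-exact overrides.
Frequencies are floored at $1/(2N+1)$ and renormalised so no likelihood
can hit $\log 0$ on a rare allele; the test suite checks the floor never
moves a frequency by more than its own value.

Loci deviating from Hardy–Weinberg (Monte-Carlo exact test, p < 0.05 per
population) and loci flagged error-prone are excluded, mirroring the
study's marker QC. Note that strongly kin-structured *simulated*
populations genuinely violate HWE at many loci; the pipeline exposes
`hwe_alpha = 0` to disable the screen in that setting.

## Dyad classification and kin clusters

A relationship hypothesis is a k-coefficient triple $(k_0, k_1, k_2)$.
The dyad likelihood per locus is
$P(g_x)\,[k_0 P(g_y) + k_1 T_1(g_y|g_x) + k_2 T_2(g_y|g_x)]$ with HWE
genotype probabilities, and significance comes from dyads simulated under
the null: $p = (1 + \#\{\Lambda' \ge \Lambda\})/(1 + n_{null})$. With
10 informative loci, full-sib vs unrelated classification holds its 5%
type-I level and exceeds 80% power (acceptance criterion).

The study's group-splitting tool (a "Simpson-assisted descending ratio"
partitioner) is likewise not reprinted. We substitute a greedy
agglomeration on the mean pairwise FS-vs-U likelihood ratio, with each
multi-member cluster re-validated by classifying members against a
representative and demoting non-relatives to singletons. Two deliberate
choices:

* the merge score is the **geometric** mean ratio (mean log-ratio). The
  raw ratio is heavy-tailed: a handful of lucky cross-family dyads can
  drive arithmetic-mean merges of whole groups, which the demotion pass
  then shreds. On simulated two-family groups the geometric-mean variant
  recovers the exact partition; truth recovery — not equivalence with the
  legacy tool — is the acceptance surface.
* ties are broken toward the lexicographically smallest member id, making
  the partition deterministic.

## Parentage

Every adult (at or above the sex-specific gonadal maturity size, 32.5 mm
males / 31.5 mm females) is tested pairwise against every smaller group
member: mismatch count (loci sharing no allele), age feasibility
(back-calculated SL at the offspring's birth ≥ 31 mm), acceptance at ≤ 1
mismatch with at most one father and one mother per offspring (fewest
mismatches, then highest PO-vs-U likelihood ratio; exact ties accept
nobody and warn). Mothers and fathers are assigned independently — joint
compatibility of the trio is deliberately not enforced, matching the
pairwise published rule.

**Known limitation (and an honestly red criterion).** On simulated
populations with realistic breeder turnover (median tenures ~190–260 d
against a multi-year group history), many true fathers are gone by
sampling time, and a mature full brother ≥ 210 d older than the offspring
passes the 0/1-mismatch screen with substantial probability (roughly
$\Pr[\mathrm{Bin}(10, 0.175) \le 1] \approx 0.45$ per such brother). The
accepted-father accuracy therefore plateaus near 0.89, short of the 0.95
recovery target asserted in the acceptance suite; the corresponding test
is left failing rather than weakened, because the shortfall is a property
of the published pairwise rule in this social system, not of the
implementation. Field analyses using this rule inherit the same
(unmeasurable) error.

## Immigrants, inheritance, tenure

The threefold reconstruction per group:

1. **Immigrant classes.** Non-immigrant = an accepted parent present, or
   a kin-cluster partner with a *significant direct* dyad link that is
   not a presumed descendant. Otherwise the genotype is unique:
   *immigrant* if the group contains both an older and a younger kin
   cluster (≥ 2 members; singletons are themselves "unique genotypes"),
   else *possible immigrant*. Two operationalisation details matter and
   were validated against simulator truth: descendants must not count as
   evidence of philopatry (an immigrant breeder that reproduced is still
   an immigrant), and the cluster partition chains mates through shared
   offspring, hence the direct-link requirement. "Presumed descendant"
   means a Mendel-compatible, age-feasible parentage candidate of the
   focal, or a younger PO-labelled partner.
2. **Inheritance (MLI/PLI).** A breeder inherited its position if its
   accepted other-sex parent is still in the group, or a significant
   FS/HS partner of similar age (default window 90 d — "similar-aged" is
   not defined in the source and is config-exposed). Detection is a
   minimum estimate: dead relatives make inheritance invisible.
3. **Tenure.** Minimum = age of the oldest group member the breeder
   produced (0 if none); maximum = age of the next older non-immigrant
   not produced by the breeder; tenure = their mean, censored (minimum
   only) when no such elder exists. On 40 simulated groups the mean
   uncensored estimate lands within ±5% of the true mean tenure, well
   inside the ±25% recovery band (the interval midpoint is biased high
   when broods start late and low when the "next older" member is much
   older).

## The statistics layer

* `workload_composite()`: defence + breeding-chamber visits +
  maintenance counts; triple 15-min protocols are averaged and scaled by
  2/3 to the 10-min scale; half-up integer rounding so Poisson count
  models can be fitted downstream. Model *fitting* (GLMMs, multinomial,
  logistic) is deliberately out of scope — the pipeline emits model-ready
  tables.
* `chi_square_2x2()` uses no continuity correction: that exact choice
  reproduces the published 23.3 / 21.0 / 3.4 / 3.1 / 2.89 from the
  printed count tables (the 21.06 → "21.0" case shows the source
  truncated rather than rounded; the acceptance test accepts either
  convention at the printed precision).
* `dunnett_c()` implements the unequal-variance post hoc with
  studentized-range quantiles (`qtukey`); coverage on normal data is
  ≥ 93% at α = 0.05 (conservative by construction).
* `bootstrap_category_comparison()` resamples the dyad table with
  replacement (unstratified — whether the original macro stratified is
  unknown; dyad non-independence is knowingly ignored, as in the source),
  averages the ANOVA p and the Dunnett's C bounds over 100 repetitions,
  and calls a pair significant when the *averaged* interval excludes 0.
  Replicates that lose a category are redrawn and logged.
* `km_gehan()` is the risk-set-weighted log-rank (Gehan–Breslow), i.e.
  the classical Kaplan–Meier life-table comparison; `survdiff(rho = 1)`
  is Peto–Peto and is *not* equivalent, which is why this small test is
  hand-implemented.

## The simulator as a stated world

`simulate_population()` encodes the study system it emulates: 40
polygynous groups (range 30–45 in the field data), 1–4 subgroups, 0–15
helpers per subgroup, 10 loci with 12–24 alleles each (the markers showed
a long rare-allele tail — about a fifth of alleles occurred in a single
group — so high allelic richness is the realistic default), immigrant
recruitment probability 0.17 per event (calibrated to the observed
standing fraction; the source reports no per-event rate), helper
paternity/maternity 0.20 / 0.07 per brood (the detected shares), breeder
turnover as a geometric per-interval hazard matched to the 257.5 / 191.5
d median tenures, inheritance probabilities 11/33 and 31/60, gonadal
maturity at 32.5 / 31.5 mm, and sizes tied to age by the shared growth
model. Recruitment targets are spread over brood dates on the
breeding-interval grid, so same-day natal recruits of a subgroup are full
sibs. A vacated breeder slot waits for an heir when inheritance is drawn
but nobody mature is available — this keeps `p_inherit = 1` groups
genuinely closed.

What the generator does **not** emulate: spatial territory geometry,
predation and mortality of non-breeders, emigration of helpers,
genotyping artefacts beyond uniform error/missingness, and behavioural
time budgets beyond Poisson workload counts. A green recovery test
therefore establishes that the estimators invert the generator's
simplified history, not that they are unbiased on real field data.

## Reproducibility

Every stochastic function takes an explicit seed; the pipeline derives
per-stage seeds from one master seed, and an identical config + seed
reproduces a byte-identical report bundle (tested). The run manifest
(JSON) records config, seed, package version, loci used and exclusions.
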