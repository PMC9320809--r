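---
title: "Courtship ethograms, behavioral Markov chains, and divergent sexual selection"
author: "courtshipSelect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Courtship ethograms, behavioral Markov chains, and divergent sexual selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(courtshipSelect)
```

## The scientific problem

Populations of *Drosophila melanogaster* of Southern-African ("Z-type") and
cosmopolitan ("M-type") origin show strong, asymmetric premating isolation:
Z-type females reject cosmopolitan males while cosmopolitan females mate much
less discriminately. Which male traits are the females actually selecting on,
and is that selection *divergent* — favoring opposite trait values in the two
female backgrounds? Answering this requires (i) a quantitative description of
male courtship from scored video (an ethogram), (ii) a test of whether males
*adjust* their courtship to the female genotype they meet (plasticity), and
(iii) standardized selection-gradient estimates per female genotype, for both
behavioral traits and contact pheromones (cuticular hydrocarbons, CHCs).

`courtshipSelect` implements that full pipeline, plus a seeded courtship
simulator with known ground truth so that every estimator in the chain can be
validated without access to any particular study's raw scores.

## Data model

Courtship is scored as one of eight state behaviors at fixed 10-second grid
points, for up to 30 minutes: `separate`, `engaging`, `singing`, `singing2`
(head-to-head singing), `scissoring`, `circling`, `attempted_copulation`, and
the absorbing terminal state `copulating`. Scoring ends at copulation.
`read_event_log()` accepts both already-gridded logs (one row per scored
timepoint) and free-timestamp state-onset logs; in both cases the state at
grid point $t$ is the last recorded state with time $\le t$, so each grid
point represents the half-open interval $[t, t+10)$ and an onset between grid
points never snaps backward. This convention makes re-gridding idempotent.

CHC quantifications arrive as per-individual GC peak areas together with a
hexacosane (n-C26) internal standard; `normalize_chc()` reports dimensionless
abundances (peak area divided by internal-standard area) and drops the
standard. Only the ratio convention is applied — no absolute-quantity
calibration — because the ratio is the only normalization that is
scale-invariant per individual, and compound names are matched through a
case-insensitive synonym map (`"7-tricosene"` and `"7-C23"` are the same
trait).

## Courtship metrics

**Initiation.** Two operational rules: the first non-`separate` timepoint
(`"first"`), or the first element of the earliest run of three consecutive
non-`separate` timepoints (`"consecutive3"`, the package default). The
stricter rule ignores brief early contacts that are broken off; the
`compare_initiation_methods()` diagnostic reports the mean and maximum
discrepancy in seconds so users can judge whether the choice matters in their
data (in typical panels the mean discrepancy is a few seconds while rare
trials differ by minutes — exactly the situation the stricter rule exists
for).

**Latency and budgets.** Copulation latency is the time from initiation to
the onset of `copulating`, the study's continuous fitness proxy. The time
budget of each behavior is its fraction of scored timepoints from initiation
up to (but excluding) copulation; post-initiation `separate` timepoints count
in the denominator, so the six active-state fractions plus the `separate`
fraction sum to 1. Trials that never copulate are scored over a window equal
to the mean successful latency of the same male-strain-by-female-strain
combination (`impute_censored_window()`); a combination with no successes has
no reference latency, which is an explicit error so the caller can fall back
to the full recording deliberately rather than silently.

**Mating index.** For combinations where failures carry real information, the
mating index replaces censored latencies with the maximum observed time (an
underestimate) and divides the mean by the proportion of trials that mated,
so larger = worse. The weighting direction is chosen so that the index
degrades smoothly to infinity as success probability goes to zero; it is
exposed as a fitness convention (`relative_fitness(..., "mating_index")`)
rather than hard-wired.

**Progeny assay.** Long-horizon isolation is assayed as days until first
progeny over 16 days, right-censored at day 16, compared between male strains
by Kaplan–Meier curves with a pairwise log-rank test against a reference
strain. The log-rank is our choice of survival comparison; it is the default
tool for comparing right-censored time-to-event curves and needs no
distributional assumption at these sample sizes.

## Plasticity: aligned-rank-transform ANOVA

Budgets are bounded fractions with ties from the 10-s grid, so factorial
effects are tested nonparametrically with the aligned-rank transform (ART).
For each effect (male strain, female strain, their interaction), responses
are aligned — each observation is reduced to its residual from its cell mean,
then the estimated target effect is added back — ranked with average ranks,
and the full two-factor ANOVA is fitted to the ranks; only the aligned
effect's F is read from each fit. With unbalanced cells (some combinations
yield more courting trials than others), the estimated effects come from
unweighted means of cell means and the F tests are Type III with sum-to-zero
coding, so tests target the same hypotheses as in the balanced case.

A female-strain main effect is the plasticity signal: averaged over male
strains, males express a different trait value depending on the female
genotype; a significant interaction means the shift is not parallel across
strains. `reaction_norms()` reports per-strain context means and the sign
pattern of the shifts.

Two numerical points deserve notice. First, when the ranked aligned responses
are fitted exactly by the factorial model, F ratios degenerate; we define
F = 0 when the effect sum of squares is zero and F = Inf when the residual
sum of squares is zero but the effect is not — the noiseless corner cases
behave as a user would predict. Second, ART is exactly invariant under
*increasing affine* transformations of the response (alignment commutes with
them and ranks are unchanged), but not under nonlinear monotone maps: the
alignment step subtracts means on the raw scale, so `exp()`-transforming a
response can change which residual is largest and hence the ranks. Users who
need full monotone invariance should rank-transform upstream and accept the
loss of interaction interpretability; the package follows the standard ART
definition and does not pre-transform.

## Courtship sequences as Markov chains

The sequence of states is treated as a discrete-time Markov chain on the
eight states with `copulating` absorbing; self-transitions are meaningful
dwell times on the 10-s grid and are retained. `count_transitions()` pools
one-step transition counts over trials within a male-strain-by-female-strain
group (never across trial boundaries), and `homogeneity_test()` asks whether
a male strain's transition matrix differs between female contexts.
Conditional on source-state totals, each source state contributes an
independent groups-by-destinations contingency comparison; the test statistic
is the likelihood-ratio G² summed over source states, with degrees of freedom
counting only rows and columns with support (so the absorbing row and
never-visited states drop out cleanly).

At realistic scale — a few hundred transitions per group spread over up to 56
cells — many cells have expected counts near 1 and the plain G² statistic is
markedly anti-conservative (we measured type-I error near 0.21 at a nominal
0.05 with 300 transitions per group). The package therefore applies the
Williams (1976) small-sample correction to each source-state table by
default, which restores near-nominal calibration (≈ 0.048 measured under the
same null); `correct = FALSE` recovers the raw G², and `method = "pearson"`
gives the Pearson variant. Per-transition plasticity is tested downstream by
feeding `per_trial_transition_freq()` fractions into the same ART machinery.

## Selection gradients

The unit of analysis is the male strain within a female context: CHCs are
measured on separate individuals from the courtship trials, and
successful-trial counts differ between combinations, so per-strain means are
used for both trait classes. Each trait is variance-standardized
($z = (x-\bar x)/s$, sample SD), making gradients comparable across traits
and contexts. Relative fitness has mean 1 by construction; the default
convention is mean-scaled *inverse* latency, so that a trait that shortens
latency receives a positive gradient and positive coefficients mean positive
selection. The literal mean-scaled latency is available as `"latency"`
(under it, signs invert), and the mating index as `"mating_index"` — the
three conventions exist because latency-based fitness can be written in
either orientation and analyses must state which they use.

The gradient itself is the slope of relative fitness on the standardized
trait *at the median* (quantile $\tau = 0.5$): the coefficients minimize
$\sum_i |w_i - a - \beta z_i|$. At strain-level sample sizes the L1 optimum
is found *exactly* by enumerating candidate lines through point pairs (the
profile loss in the slope is piecewise linear with breakpoints at pairwise
slopes), implemented in C++ with a deterministic tie-break toward the
smallest |slope|; robustness to outlier strains is the reason for
conditioning on the median. Confidence intervals are seeded case-resampling
percentile bootstrap intervals (default 2000 replicates). We chose the
bootstrap over rank-inversion intervals because rank inversion is unstable
at n ≈ 13 strains; the method and seed are stored with every result.

Mating success is modeled directly by binomial (logistic) regression of
per-strain successes/trials on the standardized trait via IRLS, with Wald
intervals; complete separation is detected and flagged rather than reported
as a huge finite coefficient. Strains with zero successful matings carry no
latency and are excluded from the gradient regression for that female (they
remain in the binomial regression, and re-enter the gradient path under the
mating-index convention).

**Variable reduction.** To limit the number of gradient tests, traits are
pre-screened with a two-stage random-forest procedure. Stage 1 averages
permutation importance over an ensemble of regression forests and keeps
traits exceeding both the typical importance-SD of the lowest-ranked half
*and* a permutation-null bar — the 90th percentile of the maximum trait
importance when the response is randomly permuted. The second bar matters:
at n of a few dozen, the best of p noise traits is genuinely correlated with
the response in-sample and carries positive out-of-bag importance, so an
SD-only threshold admits it; the permutation null measures exactly that
"best spurious correlate" scale. Stage 2 adds surviving traits in importance
order, keeping each only if it lowers mean out-of-bag error by more than one
SD of the error estimate. The procedure is deterministic given its seed, and
the union of the traits selected in the two female contexts is analysed for
both, so divergent selection on a trait picked up in only one context is not
missed.

**PCA.** `pca_traits()` decomposes the correlation matrix of per-strain trait
means (behaviors + CHCs) to display how courtship strategies covary across
genotypes; within each component the largest-magnitude loading is forced
positive, so repeated runs are sign-identical.

## The synthetic scenario

`default_config()` builds a panel of (by default) 12 male strains crossed
with two female contexts ("Zlike", "Mlike") and 5 trials per pair, 8-state
chains stepped every 10 s for at most 180 steps. Ground truth is recorded
alongside the data. Its components, and what they emulate:

* **Base dynamics** are a plausible courting male: heavy dwell (self-loop)
  probabilities, a small copulation hazard from every active state, none
  from `separate`. Per-strain multiplicative jitter (log-normal, SD 0.15)
  on transition mass creates male-strain main effects.
* **Plasticity**: in the M-like context, every strain's matrix moves half of
  each row's attempted-copulation mass into singing and inflates singing
  transition mass by 1.5x. The `singing` and `attempted_copulation` rows
  share their exit profile toward other states, so the reallocation shifts
  those two budgets specifically. At the default scale this yields a singing
  female-effect F near 30, an attempted-copulation effect near 12, and
  context-dependent transition matrices detected for roughly half the
  strains — the qualitative structure of real panels. The shift size was
  fixed once, when the scenario was designed, by requiring the plastic
  traits to be clearly detectable at the default panel size.
* **Fitness**: log latency is `log(300 s)` minus trait effects plus
  N(0, 0.35) noise; mating success is logistic with intercept 1.5. The CHC
  `cVA` carries opposite-signed effects in the two contexts (±0.3 SD⁻¹ on
  log-latency, ±0.8 on log-odds) — the divergently selected trait; `7-C25`
  is beneficial only in the Z-like context; `n-C21` and `7-C23` are
  measured but neutral. Latency is drawn first from the trait-linked model
  and the chain's copulation hazards are then rescaled (via the fundamental
  matrix) so expected absorption time matches it — keeping sequence
  structure and fitness structure independently controllable.
* **Isolation**: one strain never mates with each female context
  (asymmetric isolation), and one strain is reluctant to initiate with
  Z-like females (near-unbroken `separate` self-loop, escape probability
  0.005), exercising the non-courting exclusion rules.
* **CHCs**: per-strain log-normal profiles around seeded strain means
  (between-strain SD 0.5, within-strain measurement SD 0.2), written as raw
  peak areas against a simulated n-C26 internal standard; exposure to
  opposite-type females lowers 7-C23, mirroring reported exposure effects.

Reproducibility: per-trial seeds are drawn once from the master seed's
stream and indexed by trial counter. (Arithmetically spaced `set.seed()`
values produce correlated Mersenne–Twister streams — we observed clusters of
implausibly instant copulations under that scheme — so substream seeds are
themselves pseudo-random draws.)

**What the simulator does and does not emulate.** It reproduces the
*statistical* structure the pipeline assumes: gridded absorbing-state
sequences, genotype-pair-specific dynamics, context plasticity, trait-linked
latency and success, strain-structured CHC profiles. It does not emulate
observer error, within-trial nonstationarity (e.g. escalation), block or
time-of-day effects, or correlations between behavior and CHCs within a
strain. Passing tests on synthetic panels therefore validates the
estimators' correctness and calibration, not the biological adequacy of any
particular model for real data. One realistic artifact is worth knowing
about: because budgets are computed over the initiation-to-copulation
window, context differences in latency or success leak small apparent
"plasticity" into behaviors whose dynamics never change (we see this on
scissoring in the synthetic panels); this is a property of the
window-normalized budget definition itself, and real analyses should read
marginal female effects on slow-accumulating behaviors with that in mind.

## Problem sizes and numerical choices

The validation suite runs at deliberately chosen scales: oracle equivalence
on 200 (median regression) and 50 (binomial) random small instances;
homogeneity and ART null calibrations at 1000 replicates each (300
transitions/group and 2x12 cells with 5 replicates); gradient-sign and
null-coverage recovery on 20 panels of 50 strains with 2000-replicate
bootstrap intervals; plasticity power at 500 replicates of a 1.5 SD shift;
and transition-matrix recovery from 1e5 simulated steps (0.02 per-entry
tolerance, the binomial standard error scale at those counts). Degenerate
inputs error loudly and early: unknown behavior labels, states after
copulation, zero internal standards, zero-variance traits, empty factorial
cells, zero residual df, all-censored survival comparisons, and
sub-minimum sample sizes all have named errors rather than silent NA paths.

## Known limitations

* Gradients are simple (one trait at a time), not partial: no multivariate
  gradient vector, no quadratic/correlational selection.
* ART here has no random block terms; recording-session effects must be
  handled by design (as randomized block rotation) rather than modeling.
* The homogeneity test is asymptotic even with the Williams correction;
  with fewer than ~10 trials per group, treat marginal p-values cautiously.
* The mating-index weighting direction is one defensible reading of a
  verbally described index; it is a configurable convention, not a claim.
* Bootstrap percentile CIs at n = 13 strains are approximate; method-level
  differences (bootstrap vs rank inversion) move endpoints by more than
  numerical error, which is why every result stores its CI method and seed.
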