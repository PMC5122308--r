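---
title: "Scoring and modelling sexual display complexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and modelling sexual display complexity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdcomplexity)
library(dplyr)
```

## The measure

A focal sequence is an ordered series of discrete postures from a finite
display repertoire, recorded continuously over a fixed window (300 s by
default). Three quantities summarize it:

* **richness** `R`: the number of distinct postures used (bounded by the
  repertoire size, nine for the built-in flamingo ethogram);
* **versatility** `V`: the number of transitions between *different*
  postures;
* **SDC** `= R × V`.

Two readings of "number of transitions" are defensible, and the package
implements both. The default, `change-count`, counts every adjacent pair
of differing postures — the total number of posture changes. The
alternative, `distinct-ordered`, counts the number of *unique* ordered
posture pairs observed. We default to `change-count` because observed
versatility values in 5-minute flamingo bouts span roughly 2–17, a range
consistent with counting transition events (a distinct-pair count over a
nine-posture repertoire would saturate much earlier for vigorous
displayers), and because the analogous birdsong literature counts song
switches. The choice is a package default, not a claim about what any
particular field protocol did; `mode` switches it everywhere.

Two scoring conventions matter for edge cases. Adjacent duplicate events
are collapsed before counting, so a re-logged identical state is never a
transition. A monotone sequence therefore scores `R = 1`, `V = 0`,
`SDC = 0`; zero scores are kept, not excluded, even though real datasets
may never contain them. Sequences shorter than the full window are
discarded by `filter_complete()` rather than rescaled: a display bout
interrupted and resumed is not spliced, because switching rate is not
stationary across an interruption.

## Predictor standardization

All continuous and binary predictors are centered and divided by **two**
sample standard deviations, so each standardized column has mean 0 and SD
0.5 and a one-unit change spans roughly the "low vs high" contrast of a
binary input. Binary sex (F = 0, M = 1) is standardized by the same rule
as the continuous columns — a uniform rule is easier to reason about and
to invert at prediction time, at the cost of a slight difference from
conventions that leave binaries untouched. The quadratic age term is
squared on the raw scale *first* and then standardized as its own column;
the scaling record (per-column center and scale) is carried on the data
and reused verbatim when standardizing prediction grids, so a prediction
at age 20 always means 20 years.

One consequence worth knowing: raw `age` and `age²` are highly collinear
over a 4–37-year span, so their individual standardized coefficients can
be large and anticorrelated while the fitted curve itself is stable. All
curve-level outputs (peak location, predicted values) are unaffected;
single-coefficient magnitudes should be read with the collinearity in
mind.

## Candidate models, AICc, and averaging

`generate_model_set()` enumerates every subset of the full term list
subject to marginality — `age²` never enters without `age`, an
interaction never without both mains — plus configurable exclusion pairs
for collinear predictors (default: group size and date of season may not
co-occur, since display groups grow as the season advances). The
intercept-only model is always included. For the nine-term display model
this yields 112 candidates.

Each candidate is fitted by maximum likelihood (`stats::glm`). The AICc
parameter count `k` includes the intercept, the slopes, and — for
gaussian models only — the residual variance. This convention is the one
under which the published model-selection arithmetic we use as a fixture
reproduces exactly (a gaussian three-slope model has `df = 5`, a binomial
one-slope model `df = 2`). `AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1)` is
reported unrounded and is undefined (an error) when `n ≤ k + 1`. Ranking
ties are broken by fewer parameters, then label order, for determinism.
Binomial candidates showing complete separation are flagged and dropped
from ranking with a warning rather than contaminating the average with
divergent coefficients.

Averaging uses the **zero method** (full average) over the ΔAICc ≤ 2 set
with weights renormalized within that set: a model that excludes a term
contributes a zero coefficient with zero variance. The unconditional
standard error follows the usual model-selection-uncertainty form
`SE = Σ w_i √(var_i + (β_i − β̄)²)`, and confidence intervals are
normal-theory `β̄ ± z₀.₉₇₅·SE`. We fix the plain-SE, normal-quantile
convention rather than reverse-engineering any published interval; the
tests check the averaging arithmetic against hand-computed fixtures only.
A term's importance is the summed renormalized weight of the top models
containing it, so a term in every top model has importance 1.

Predictions (`predict_response()`) standardize new inputs with the stored
scaling record, derive `age²` from `age` automatically, hold unspecified
model columns at their standardized mean (0 — which, under the zero
method, is also the value at which an averaged-out term contributes
nothing), apply the inverse logit for binomial responses, and flag
extrapolation beyond the fitted range instead of refusing it.

## Rank tests and the randomization null

`wmw_test()` and `signed_rank_test()` use exact enumeration when the
smaller sample has ≤ 12 observations and there are no ties, and otherwise
a normal approximation with tie-corrected variance and *no* continuity
correction. Enumerating all possible statistic values at group sizes 8–12
shows the two paths never differ by more than 0.047 in the two-sided p;
the test suite asserts that bound. Degenerate inputs (identical samples,
all-zero differences) return p = 1 with a flag.

The assortative-mating test permutes the female attribute vector against
the fixed males — re-pairing the observed individuals only, identity
permutation allowed, 1000 simulations by default — and reads the 2.5th
and 97.5th percentiles (linear interpolation between order statistics) of
the simulated mean absolute within-pair differences as the random-mating
band. The verdict is purely positional (`inside`, `outside-low` =
assortment, `outside-high` = disassortment); no p-value is attached,
because interval position is the quantity of interest. Permuting males
instead of females gives the same null distribution, which the suite
checks. When the trait was not measured on the paired individuals,
`predicted_sdc_for_pairs()` assigns each member the complexity predicted
from its age with the date held fixed for everyone (day 94 = February 3
by default), making the assigned score a pure function of age — which is
also why a symmetric fitted quadratic can make a very old and a very
young bird near-identical in predicted complexity despite a 28-year age
gap.

Every stochastic operation takes an explicit integer seed and restores
the global RNG state on exit; a study regenerates bit-identically from
`(config, seed)`.

## What the synthetic generator emulates

The generator produces a cohort mirroring a single field season: 100
focal individuals (50 female, 50 male), integer ages uniform on 4–37,
observation dates uniform over a 152-day November–March season (day 0 =
November 1), display groups of 9–130 birds, daylight hours, a 56-bird
focal-year subset with assessable breeding status, and 21 both-ringed
pairs.

Display behavior is driven by a latent quality
`q = q_age·age + q_age²·age² + q_date·date + N(0, σ_q)` with defaults
(`q_age = 0.16`, `q_age² = −0.004`, `q_date = 0.004`, `σ_q = 0.25`)
chosen to put the age peak at 20 years — matching the qualitative
early-improvement-then-senescence profile the analysis is designed to
detect — and a positive season trend. Sequences are first-order Markov
chains: event count `~ 1 + Poisson(30)`, switch probability
`plogis(qlogis(0.08) + 1.1·q)`, accessible-posture set of size
`clamp(2 + round(2.5·q), 2, 9)`. These sequence defaults were fixed once
so that generated scores fall inside the field-observed ranges (richness
2–8, versatility 2–17, SDC 4–136) for ≈ 90–95 % of sequences, with
cohort means near the observed averaged intercepts (R ≈ 5.4, V ≈ 9.7,
SDC ≈ 55–58). The expected change count is `(E[events] − 1)·s(q)`, which
the suite verifies against Monte-Carlo means.

Breeding is Bernoulli with `logit p = −1.33 + 1.42·z(SDC)` (two-SD
standardized within the cohort), giving ≈ 21 % prevalence at average
complexity and a positive complexity effect of the magnitude reported for
the colony-observation analysis. Pairs form by rank-matching the sexes on
age-predicted quality with Gaussian rank jitter of SD
`n_pairs·(1−ρ)/ρ`; `ρ = 0` is exactly uniform random mating, `ρ = 1`
exact rank matching (which minimizes the mean absolute difference over
all matchings).

What the generator deliberately does **not** emulate: within-individual
repeatability (one sequence per bird — the design is cross-sectional),
diurnal or social-contagion structure in sequences, selective
disappearance of poor-quality individuals with age, and any dependence of
group size on date (the two are independent in the generator, so the
collinearity exclusion is exercised as configuration, not forced by the
data). Passing tests therefore demonstrate that the *pipeline* recovers
the structure it assumes, not that real display data satisfy those
assumptions.

## Problem sizes and runtime choices

The stochastic test properties use sizes chosen to keep Monte-Carlo error
well below the asserted margins: 500 replicate experiments for
randomization-test calibration (≈ 5 % type-I at `ρ = 0`, three-SE band)
and power (> 50 % detection at `ρ = 0.9`, 21 pairs, 1000 simulations
each); 50 synthetic cohorts of n = 100 for quadratic-age recovery (the
best model contains `age + age²` in ≥ 90 % and the averaged quadratic is
negative in ≥ 95 %); 2000 sequences for the Markov change-rate check; and
exhaustive enumeration oracles for the rank tests up to n = 8.

## Known limitations

* The gaussian display models treat `SDC = R × V` — a product of counts —
  as continuous with additive errors; this matches the analysis the
  package reproduces, but the score is right-skewed and heteroscedastic,
  and a count-model variant is out of scope.
* Zero-method averaging shrinks terms toward zero by construction; with
  the collinear `age`/`age²` pair always retained together, individual
  coefficients are interpretable mainly through the prediction curve.
* The randomization null re-pairs only the observed pair members; if real
  pairs formed from a larger candidate pool, the null is conditional on
  the observed marginals.
* Exact rank tests switch to the normal approximation in the presence of
  any tie; midrank handling is inherited from `stats::wilcox.test`.
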