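---
title: "Measuring urban poverty from household surveys: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring urban poverty from household surveys: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanpoverty)
```

## The problem

Household survey programmes of the DHS/MICS type are often the only
population-representative data available for the large cities of low- and
middle-income countries, and they carry enough information — asset
ownership, housing materials, water and sanitation access, education of
household members — to classify households as poor or not poor in several
ways. The classifications disagree, their poorest groups differ wildly in
size, and an analyst comparing many cities must pick one. This package
implements that whole workflow as reusable, tested code: seven household
poverty classifiers, a reproducible procedure for choosing among them, five
welfare outcomes, a city performance typology, and correlations of city
results with macro-level development indices. A synthetic multi-city
generator stands in for the restricted-access survey microdata so every
stage can be exercised offline.

## The seven poverty classifiers

All classifiers operate at the household level.

**Relative measures (4).** The wealth index is the first principal component
of a standardised matrix of asset and housing indicators, the standard
DHS/MICS construction. `compute_wealth_score()` performs the PCA on the
*weighted* correlation matrix (weights enter the means, variances and
covariance), orients the sign so that higher = richer, and
`classify_relative_poor()` cuts the weighted percentile distribution at
30, 40, 50 and 60 percent (`poor_w30` … `poor_w60`). When the survey ships
its own wealth score, `validate_against_provided()` compares the recomputed
score against it and the pipeline adopts the original score when |r| ≥ 0.95
(sign-flipping if needed), recomputing otherwise.

Percentile ranks use the weighted mid-distribution convention: the rank of
a household is the weight strictly below it plus half the weight tied with
it, over total weight. This makes ranks deterministic under ties, invariant
to row order and to weight rescaling, and it forces the cut-offs to nest
(the 30% poor are a subset of the 40% poor, and so on). The realised
weighted poor share can differ from the nominal share by at most one
household's weight share. Ranks use household weights, not
weight × members; both the rank weighting and the cut-off list are
arguments, so a population-weighted variant is a one-line change at the
call site.

**Poverty line.** Incomes are not observed; the predicted-income approach
assigns each household the income quantile matching its wealth rank under a
lognormal model. The lognormal Gini identity `G = 2Φ(σ/√2) − 1` gives
`σ = √2 Φ⁻¹((G+1)/2)` from the city's Gini index, and the mean anchors on
GDP per capita corrected for consumption expenditure. Two corrections are
implemented because the combination of the two World-Bank consumption
series is not uniquely determined: the default multiplies GDP per capita by
the ratio of the household consumption share to the total consumption
share; the alternative (`hh_share_of_gdp`) uses the household share of GDP
directly. Predicted annual income at rank r is `exp(μ + σΦ⁻¹(r))` with
`μ = log(mean) − σ²/2`; dividing by household members and by 365.25 yields
a daily amount compared strictly against the US$ 1.9 line. The division by
members is itself ambiguous in the source methodology (the prediction can
be read as household-level or per-capita income); the default `household`
mode divides, and a `percapita` mode skips the division. Under `percapita`
mode the poor share has a closed form, `Φ((ln z − μ)/σ)` for line z, which
the tests use as an analytic oracle. Ranks of exactly 0 or 1 are clamped to
`[ε, 1−ε]` with `ε = min(1/(2n), 10⁻⁴)` so the quantile function stays
finite; interior ranks are never modified.

**Socioeconomic deprivation status (SDS).** Eight deprivations in two
dimensions. Education: a school-aged child out of school; no member aged
10+ with at least six years of education. Living standards: no electricity,
no improved water, no adequate sanitation, non-durable housing materials,
asset deprivation, and dirty cooking fuel. The published indicator list
names five living-standards items and states a count of six; the sixth here
is cooking fuel, taken from the multidimensional-poverty tradition the
measure is adapted from, and the asset rule (owns at most one small asset
and no car) is likewise the conventional stand-in for a list defined only
in secondary sources. Weights are nested-equal — each dimension carries
1/2, so education items weigh 1/4 and living-standards items 1/12 — and a
household is deprived when the weighted score reaches 1/3. Weights and
threshold are arguments and are recorded in the exported run record.

**UN-Habitat slum definition.** A household is a slum household if it lacks
any of: durable housing (floor, wall and roof all durable), sufficient
living space (≤ 3 persons per room), safe water access (improved source
with a round-trip fetch time under 30 minutes), adequate sanitation
(improved and not shared). Security of tenure, the fifth criterion, is not
measurable in these surveys and is omitted. A household with a definite
failure on any criterion is a slum household even if another criterion is
unevaluable; a household whose classification is genuinely indeterminate
(e.g. shared-flag missing on an improved facility, everything else met) is
excluded with an NA rather than defaulted to deprived, to avoid inflating
slum prevalence.

## Choosing the preferred measure

The selection procedure is frozen into an explicit three-step rule
(`select_preferred_measure()`), so the choice is reproducible rather than
narrative:

1. *Feasibility.* Keep measures whose median poorest-group unweighted count
   across cities is at least `min_n` (default 100). Small poorest groups
   make the outcome prevalences unusable.
2. *Comparability.* Among surviving relative measures, keep those whose
   median observed agreement with **every** absolute measure reaches the
   threshold (default 0.60). Observed agreement is the share of households
   given the same poor/rich label by the two measures — unweighted by
   default, since each household is one classification decision; a weighted
   mode exists.
3. *Discriminatory power.* Pick the survivor with the largest mean absolute
   median gap across the five outcomes; exact ties go to the smaller
   cut-off, which favours the more selective definition of poverty.

Every step's value for every measure is returned in a decision record, and
an empty survivor set produces an explicit no-selection result naming the
step that emptied it. Medians across cities are always unweighted — each
city counts once.

## Outcomes, gaps, performance classes and context

The five outcomes (`compute_outcomes()`) are: any school-aged child
(default ages 6–14, configurable; no canonical school-age range is defined
by the surveys) out of school, with childless households counted as not
deprived so denominators stay comparable; low education, defaulting to the
"no member aged ≥ 10 with ≥ 6 years" reading (the source states the
indicator two inconsistent ways; the `any_member` literal reading is also
implemented); no electricity; no improved water, with the 30-minute
round-trip threshold inclusive ("30 minutes or longer"); and no adequate
sanitation (unimproved, none, or improved-but-shared). Missing inputs
propagate to NA and drop out of both the numerator and denominator of
`weighted_prevalence()`, which always reports the unweighted count actually
used.

Gaps are rich-minus-poor differences in weighted prevalence, so negative
gaps mean the poor fare worse. City performance on an outcome combines a
prevalence band (low < 5%, intermediate 5–15% inclusive of both edges,
high > 15%) with an inequality band (|gap| ≤ 5 pp is low): low/low is good,
intermediate/low and low/high are intermediate, and everything else is
worse. The narrative rule leaves high-prevalence/low-inequality unassigned;
it is classed worse here, because a high burden equally shared is not good
performance. The band-edge conventions (5 and 15 belong to intermediate,
|gap| = 5 is low inequality) are fixed in `performance_rule()` and the
quadrant prevalence defaults to the overall city prevalence
(`prevalence_basis = "overall"`), with the poor-group basis available.

City-level correlations (`context_correlations()`) are plain Pearson
coefficients of each outcome statistic (poor prevalence, rich prevalence,
gap) against the HDI and its health, education and income sub-indices, with
95% intervals from the Fisher z-transform `tanh(atanh r ± 1.96/√(n−3))`;
cells with fewer than 4 cities or zero variance are flagged undefined
rather than dropped silently. No multiplicity adjustment is applied across
the 60 cells, and no design-based variance is attached to any prevalence —
the pipeline reports point estimates with their supporting n.

## What the synthetic generator emulates

`generate_scenario()` creates the study conditions the pipeline assumes: by
default 38 cities of 500–2,000 households. Each household carries a latent
socioeconomic factor z ~ N(0, 1); every observed variable is a noisy
monotone function of it. Binary assets and electricity are Bernoulli with
logits linear in z (loadings 0.3–1.8, baselines set so prevalences span
roughly 10–70%, as in urban SSA samples); water source, sanitation,
housing materials and cooking fuel first draw an improved/durable/clean
class with probability rising in z, then a concrete dictionary code within
the class, so every branch of every classifier is exercised. Rosters have
1–15 members (truncated shifted-Poisson, mean ≈ 4.6); adult education is
normal around 7 years plus `education_gradient` (default 2) years per
latent SD, capped by age; school attendance has a baseline around 90% with
a positive logit gradient. Weights are uniform on [0.5, 2] normalised to
mean 1 per city — true design weights are unavailable, and this preserves
the weighted/unweighted distinction the estimators must respect — and
clusters are contiguous blocks of 25 households. City contexts draw Gini
and GDP per capita within configured ranges (GDP monotone in the city's
mean z), and the three HDI sub-indices are noisy probit transforms of mean
z, averaged arithmetically into the HDI.

The hidden factor is emitted in a `latent_ses` diagnostics column that no
analysis stage reads; it exists so tests can measure parameter recovery
(the PCA score correlates > 0.8 with it in every default-scenario city).

What the generator does *not* emulate: spatial clustering of deprivation
beyond cluster labels, informative sampling (weights are independent of z),
item nonresponse patterns, real DHS recode layouts, and any particular
country's asset mix. Passing tests therefore demonstrate the estimators'
correctness and the pipeline's internal coherence under a known generative
model — not that any substantive finding about real cities is reproduced.

## Numerical and testing choices

Determinism is end to end: every generation call derives its RNG stream
from the scenario seed and a per-city offset, restores the caller's RNG
state afterwards, and the written manifest reloads into a configuration
that regenerates the scenario byte for byte. Degenerate inputs fail loudly:
empty estimation domains, all-missing scores, zero-variance correlation
inputs and out-of-range parameters raise classed errors instead of
returning 0 or NA. Zero-variance PCA indicators are dropped with a warning;
missing PCA cells are mode-imputed (within the input table) with a logged
count, which only affects the PCA input, never the outcome indicators.

Test problem sizes are chosen to keep the whole suite fast while leaving
the statistical checks well-powered: oracle-equivalence tests run 100
seeded random fixtures of 8–40 households against brute-force loop
implementations at 10⁻¹² tolerance; the closed-form poverty-line headcount
uses a single 2,000-household city (2 pp tolerance); structure-recovery
tests use the full default 38-city scenario once; replicate-based
invariants (e.g. the poor lacking electricity more often) use 60 replicates
of 250-household cities.

## Known limitations

The lognormal income model inherits all the fragility of predicting income
from a wealth rank: it is exact only in distribution, not per household,
and the consumption correction and member division each have two defensible
readings (both implemented, defaults documented above). The SDS asset set
and sixth indicator are conventional stand-ins. Agreement is raw
concordance, not chance-corrected, by design. And the selection rule, while
reproducible, hard-codes judgement calls (thresholds, tie-breaks) that
users with different priorities should override through its arguments.
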