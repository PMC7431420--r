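---
title: "Pre-breeding social networks and breeding ecology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-breeding social networks and breeding ecology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploversoc)
```

`ploversoc` implements an analysis pipeline for a question in behavioural
ecology: how does the social structure of a resident shorebird population
outside the breeding season relate to who breeds with whom, where and when
nests are placed, whether they succeed, and whether birds move between
habitats in consecutive years. This vignette is the package's own account
of the models, the randomisation inference, the synthetic-data generator,
and the design decisions that were genuinely open.

## From resightings to a social network

The raw material is a stream of resightings of colour-ringed individuals
during repeated non-breeding surveys: one row per detection, with a 10-min
sampling-period identifier and planar coordinates in metres. Three steps
turn this into a weighted social network per year.

1. **One position per bird per period.** Repeat detections of a bird
   within one sampling period are collapsed to their mean coordinate
   (`deduplicate_sightings()`). The grouping step below needs a single
   position per bird; the mean is the least-committal summary. Conflicting
   sex records for one ring id are rejected rather than guessed.

2. **Pre-breeding window.** Sightings within 14 days of the start of the
   breeding season (1 August in the generator) are excluded
   (`filter_prebreeding()`), so that early breeding behaviour does not
   contaminate "pre-breeding" sociality. A 30-day window and a drop-May
   variant are available as sensitivity analyses and are pure subsets:
   exclusion is by calendar arithmetic only.

3. **Gambit of the group with a 20 m chain rule.** All birds detected in
   the same 10-min period are partitioned into groups: two birds belong to
   the same group if they are connected by a chain of inter-bird distances
   each at most 20 m (`assign_groups()`); everyone in a group is assumed
   to be associating pairwise. Formally groups are the connected
   components of the thresholded distance graph, computed with igraph.
   The chain boundary is **inclusive** (distance exactly 20 m joins a
   group). Conventions differ on this point in the literature, so it is a
   documented default and `chain_distance` is a parameter; the test suite
   exercises both an inclusive and a just-exclusive variant.

Edges are weighted by the **simple ratio index**,

$$\mathrm{SRI}_{AB} = \frac{x}{x + y_{AB} + y_A + y_B},$$

where $x$ counts periods with $A$ and $B$ in the same group, $y_{AB}$
periods with both observed but apart, and $y_A$, $y_B$ periods with only
one observed. The denominator is simply the number of periods in which at
least one member of the dyad was observed; a never-observed dyad has SRI
0 by convention. `sri_matrix()` computes all dyads at once with
cross-products of incidence matrices and is tested for exact agreement
with the literal per-dyad count (`compute_sri()`).

Node metrics are degree (associates with SRI > 0), strength (summed
incident SRI), and the proportion of a node's associates that are male
(undefined for isolates). Degree counts strictly positive edges because
"number of associates" is a statement about realised relationships, not
about the dyad universe. Networks are year-specific; no cross-year edges
exist. Coordinates are treated as planar metres throughout — the study
extent of a few kilometres makes geodesic corrections irrelevant.

## Breeding structure

Nests carry pair identities, coordinates, habitat, the clutch laying
date and the end of incubation, and a success flag (at least one egg
hatched). Two nests are **concurrent** when the closed day intervals
[laid, incubation end] share at least one calendar day
(`incubation_overlap()`); the interval convention is closed on both ends
because sharing a single day counts. `focal_context()` summarises each
nest's temporal and spatial neighbourhood: the number of concurrent
nests, mean and minimum Euclidean distance to them, how many lie within
100 m (boundary inclusive), and the proportion of those within-radius
concurrent neighbours that were successful. Two exclusions apply: the
focal nest itself, and any nest belonging to either member of the focal
pair — a bird's own replacement nest, or its partner's, is not a
"neighbour". Whether the original field analyses excluded partners' nests
is not stated in the source material for this design; excluding them is
the conservative choice and is applied consistently.

Julian laying date (day of year) enters success models with linear and
quadratic terms and is variance-standardised over the analysis dataset
first, which removes the strong correlation between a raw date and its
square.

**Dispersal** records are built per individual for consecutive-year
transitions only: previous fate and habitat, whether the bird stayed in
the same habitat (label comparison, with polygon containment as the
fallback when labels are missing), the distance between the two nests,
and the previous nest's neighbour-success summary. Where an individual
has several nests in a year the earliest-laid one is used, and the
fixed-effects (GLM) analyses additionally keep only each individual's
first transition, mirroring the repeated-measures structure of the
mixed-model analyses.

## Models and likelihood-ratio tests

All models are specified in `analysis_registry()`: eighteen entries
covering sex differences in sociality (datastream null), pair formation
versus SRI (mate-identity null, with a habitat-constrained variant),
nest success versus pair SRI, breeding synchrony and nest spacing versus
degree/strength (nest-randomisation null), dyadic concurrency and
distance versus SRI (nest null), nest success versus breeding structure
(with a VIF check), and the three dispersal analyses. Binary and
proportion responses use binomial errors, counts Poisson, continuous
distances Gaussian with a log link (distances are offset by +1 m so
that zero distances are representable; the offset is configurable in the
dataset builder). Reference levels for year and habitat factors are the
default alphabetical/numeric ordering.

Mixed models (lme4) are always fitted by maximum likelihood
(`REML = FALSE`) so that likelihood-ratio tests between nested fits are
valid. The focal LRT compares the full model to the model with the focal
term removed, on identical rows; the statistic is floored at zero and
compared to a chi-square with degrees of freedom equal to the parameter
difference. Random terms whose grouping factor has fewer than two levels
in a particular dataset are dropped with a message (a single transition
year, for example), as are single-level fixed factors; this makes every
registry analysis well-defined on small simulated datasets without
silently changing any estimable term. Variance inflation factors are
computed from first principles as $1/(1-R^2_j)$ of each design column
regressed on the others, and are cross-checked against `car::vif()` in
the tests.

## Randomisation inference

Three null schemes, all measure-preserving on their stated strata:

- **Data-stream permutation** (`datastream_randomise()`): within each
  sampling period, individual identities are shuffled uniformly across
  the period's group slots. Group count and sizes per period, and the
  set of individuals observed in each period, are conserved exactly, so
  the null respects the observed sampling pattern — who was seen, how
  often, and in groups of what size — while breaking who was with whom.
- **Mate randomisation** (`mate_randomise()`): female identities are
  permuted among breeding pairs within a year, or within year × habitat
  for the habitat-constrained variant that asks whether a sociality—
  pairing association survives complete habitat fidelity. Permuting
  females rather than males is arbitrary and inconsequential; the
  choice is fixed and documented.
- **Nest randomisation** (`nest_randomise()`): the tuples (x, y, laid
  date, incubation end) are permuted jointly among nests within year ×
  habitat, keeping pair identities and fates on their rows. Within-
  stratum distance multisets are conserved by construction.

The permutation statistic is the focal fixed-effect coefficient,
recomputed on each randomised dataset. Two-tailed p-values use the
add-one inclusion convention, $p_{\uparrow} = (1 + \#\{b \ge
b_{obs}\})/(n+1)$ and likewise downward, doubling the smaller tail and
capping at 1. The doubling rule is the package default because it is the
standard recommendation for two-sided permutation inference from tail
fractions; an alternative that measures extremity as absolute deviation
from the null mean is available via `method = "deviation"`. Permutation
p-values are therefore never zero, and with the observed statistic drawn
from the null they are super-uniform (both properties are tested).
Replicates whose model fit fails are dropped and counted; more than 10%
failures aborts the test, since a null distribution missing a tenth of
its mass is not trustworthy. Inside permutation replicates the
fixed-effects GLM coefficient is used by default (`mixed_null = FALSE`):
it is orders of magnitude faster than refitting a GLMM ten thousand
times and the permutation test's validity comes from the randomisation
scheme, not from the statistic's model being rich.

Each replicate runs under its own RNG substream derived from the seed,
so results are reproducible and independent of execution order.

## The synthetic-data generator

The generator stands in for the field data and defines the study
conditions the tests assume. Its defaults were fixed once, to emulate
the system the pipeline was built for: a resident population of about
120 adults, roughly 80% colour-ringed, an even sex ratio, 90% of birds
in socially monogamous pairs, three rectangular habitats (saltmarsh,
grassland, semi-desert) of which the first two are surveyed, four study
years, and an August–December breeding season with 26-day incubation.
Survey effort (20 survey days of eight 10-min periods per year,
detection probability 0.08) and the communal-patch mechanism (each bird
uses the two patches nearest its home-range centre, being at one with
probability 0.45 when detected; eight patches per habitat per year) were
chosen so that default networks reproduce the qualitative regime of the
motivating system — sparse networks (density well under 0.05, typically
around 0.02) with mean degree of order one and few repeat sightings per
bird. Per-survey detection rates for the real system are not published,
so these are regime-matching choices, not measurements.

Two generative dials carry the ground truth used in parameter-recovery
tests:

- **Pair-bond attraction** q: when both members of a bonded pair are
  detected in a period, the female is placed within the chain distance
  of the male with probability q. `ground_truth(true_sri_effect = e)`
  maps an effect strength to $q = 1 - e^{-e}$; e = 0 switches the
  process off entirely. Because partners are drawn uniformly at random
  between the sexes — independent of habitat and space — e = 0 makes
  pairing exactly independent of the sighting stream, so the
  pairing-versus-SRI null is generatively true and the type-I error of
  the full test (simulate → network → model → mate randomisation) can
  be calibrated honestly. The calibration uses 100 datasets × 500
  permutations (48 adults, two years each) and counts datasets whose
  dyad table has no SRI variation as non-rejections: such datasets carry
  no evidence either way. Power is estimated the same way at a strong
  effect (e = 3, q ≈ 0.95) over 50 datasets.
- **Dispersal stay probabilities** by previous fate, defaulting to 0.891
  after success and 0.667 after failure — the regime reported for the
  motivating system — with nest success at 0.6 and a pair nesting in a
  given year with probability 0.85. Initial nest habitat follows the
  female's home habitat with probability `habitat_fidelity`; transitions
  between consecutive nests follow the stay probabilities. The two dials
  are deliberately separate: fidelity shapes where breeding starts,
  the stay probabilities shape movement, and a logistic fit to the
  generated dispersal records recovers the stay log-odds ratio within
  Monte-Carlo tolerance in the tests.

What the generator does **not** emulate: movement realism (no correlated
random walks, tides or weather), detection heterogeneity among
individuals, divorce and re-pairing within seasons, or floaters
breeding without a stable bond. Passing tests on synthetic data
therefore demonstrate that the pipeline's machinery is correct and that
its inference is calibrated under the stated generative assumptions —
not that any particular field dataset satisfies those assumptions.

## Numerical and degenerate-input choices

- SRI of a never-observed dyad is 0 (zero denominator).
- `prop_male_associates`, neighbour distances and neighbour-success
  proportions are `NA` (not 0) when undefined; model builders filter
  complete cases per analysis.
- A constant response is flagged `degenerate` and reported with zero
  slopes rather than fitted through a separating likelihood.
- Perfect collinearity reports `VIF = Inf` rather than failing.
- Ties at the chain-rule boundary are inclusive; ties at the 100 m
  neighbourhood radius are inclusive.
- Permutation p-values are computed only from finite replicate
  statistics, with the failure count reported alongside.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at deliberately moderate sizes: the default four-year population
for descriptive and LRT checks, 48-bird two-year populations for the
100 + 50 calibration datasets, 500 random instances for the grouping
oracle, and 1,000 randomisation replicates for the conservation checks.
These sizes give stable Monte-Carlo estimates for every asserted
property; all thresholds (type-I in [0.01, 0.10], power ≥ 0.8,
binomial intervals) were fixed before the corresponding experiments
were run.

## Known limitations

- The mate-randomisation fast path refits only the response, which is
  exact for that scheme but means crossed random effects are not refitted
  within replicates; the `mixed_null = TRUE` escape hatch exists where
  runtime permits.
- Gaussian log-link mixed models rely on `lme4::glmer` with a Gaussian
  family, which can be fragile on small datasets; failures fall back to
  the fixed-effects GLM with a message, and the fallback is visible in
  the result object.
- Habitat polygons are axis-aligned rectangles by default; arbitrary
  polygons are supported through GeoJSON input and ray-casting
  containment, but the generator only places birds in rectangles.
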