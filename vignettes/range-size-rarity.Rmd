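---
title: "Range size, rarity and phylogeny: models and design choices"
author: "phyrange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range size, rarity and phylogeny: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyrange)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the choices made where the design was genuinely
open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The question and the data

Epiphytes are concentrated in a handful of species-rich angiosperm
lineages, and range size is phylogenetically conserved. An ordinary
regression of range size on lifeform therefore confounds two things: the
properties of epiphyte-rich clades, and the effect of the epiphytic habit
itself. The package's core comparison is between an ordinary model (which
describes the species pool and is the relevant summary for species-level
conservation prioritisation) and a phylogenetic model (which isolates the
lifeform effect by modelling the covariance of residuals among
relatives). The inputs are a species checklist (lifeform, family, native
botanical countries — the standard recording units of the World
Geographical Scheme), herbarium occurrence records (georeferenced and
not), and one or more species-level phylogenies.

Hemi-epiphytes are outside the lifeform dichotomy and are rejected (or
dropped, with a log) by the checklist reader.

## Cleaning

Georeferenced and non-georeferenced records take distinct paths.

**Georeferenced**, in order: native-range filter, coordinate-precision
filter, suspect-coordinates filter, duplicate removal and spatial
thinning. The order is a design choice — the records discarded by the
cheap, unambiguous filters should not occupy thinning cells — and the
audit report (`filter, arm, records_in, records_removed`) makes it
explicit and checks conservation at every stage.

- *Native range*: a record is kept iff its point falls inside a polygon of
  any native botanical country of its species, with the boundary counting
  as inside (a collection on a shared border should not be discarded for
  being on the wrong side of a line of zero width). Point-in-polygon is a
  ray-casting test with an explicit on-segment check.
- *Precision*: records with stated coordinate uncertainty above 100 km are
  removed (strict `>`: exactly 100 km is kept). Records with *missing*
  uncertainty are retained: most herbarium records lack the field, and
  removing them would discard the bulk of the data for poorly known
  species — exactly the species the rarity analysis cares about. Negative
  uncertainties are removed as invalid.
- *Suspect coordinates*: latitude equal to longitude, either coordinate
  exactly zero (comparisons on the parsed decimal values, not rounded
  ones), or the point within a buffer (default 1 km, configurable) of a
  reference point — a country centroid, capital or biodiversity
  institution, the classic geocoding artefacts.
- *Duplicates and thinning*: per species, records identical after
  rounding to 3 decimal places (~111 m at the equator) are duplicates;
  among the survivors at most one record per 110 m x 110 m grid cell is
  kept. The "110 m" cell is interpreted as a square of side 110 m — a
  literal 110 m² cell (side ~10.5 m) would be finer than the 3-dp
  rounding that precedes it and could never remove anything. Cell indices
  are `floor(metres / cell)` under an equirectangular projection at each
  record's own latitude. Ties keep the first record in input order, so
  the filter is deterministic.

**Non-georeferenced**, per species, sequentially: duplicated collection
locality (case-folded, whitespace-collapsed, punctuation-stripped — so
"Mt. Kinabalu trail" and "mt  kinabalu  trail" collide); duplicated
(year, administrative unit) pair when both fields are present; and
country codes that map to no native botanical country via the atlas's ISO
mapping (records with missing country code pass this step). Either
duplicate rule alone suffices to remove a record; they are applied in the
order listed.

## Range-size metrics

- `n_botanical_countries`: the size of the native region set; defined for
  every species.
- `specimen_count`: cleaned records summed over both arms. Computed only
  for species in four or fewer botanical countries — the metric targets
  small-ranged species, and up to four botanical countries can meet at a
  point, so even tiny ranges can span four units. A species with zero
  cleaned records gets a missing count by default ("never collected" is
  not evidence of abundance zero in a dataset defined by collections); a
  config flag records an explicit 0 instead.
- `eoo_km2`: the convex hull of the cleaned georeferenced points (three or
  more required), built in the lon-lat plane and evaluated as a geodesic
  polygon on a sphere of authalic radius 6371.0072 km. A projection-free
  spherical area was chosen over an equal-area projection because it is
  deterministic, has a closed-form oracle (the spherical zone), and agrees
  with a planar equal-area computation to well under 0.5% at the small
  extents (< 5 degrees) this metric targets — both agreements are asserted
  in the tests. Exactly collinear point sets get EOO 0 with a degeneracy
  flag rather than exclusion, so they still count as maximally small
  ranges downstream. Point sets spanning the antimeridian are recentred
  first; sets spanning more than 180 degrees of longitude or approaching
  the poles are errors, not silently wrong areas. EOO is reported at full
  precision — no flooring — since real minima reach hundredths of a km².

## The regression layer

All three fitters are written from first principles and return the same
S3 object (`range_fit`) with the usual methods (`summary`, `coef`,
`vcov`, `predict`, `residuals`, `simulate`, `plot`, `confint`).

**GLS.** For covariance `V`, `beta = (X'V^-1X)^-1 X'V^-1 y` is computed
by whitening with the Cholesky factor of `V` and solving the resulting
ordinary least-squares problem by QR — never by forming an inverse. The
log-likelihood uses the ML variance `e'V^-1e/n`; standard errors use the
REML-flavoured `e'V^-1e/(n-p)`. Mixing the two mirrors common
comparative-methods practice: lambda is profiled under ML (so
likelihoods are comparable across lambda), while coefficient uncertainty
retains the degrees-of-freedom correction.

**PGLS with Pagel's lambda.** The Brownian covariance `C` has
`C[i,j]` equal to the shared root-to-MRCA path length; the lambda
transform scales only the off-diagonal entries. The search is bounded to
[0, 1]: values above 1 can make the matrix non-positive-definite on
ultrametric trees, and 0/1 are meaningful endpoints (independence, full
Brownian structure). Profile likelihood is maximised by Brent's method
(tolerance 1e-6) with both endpoints evaluated explicitly, so boundary
optima are exact rather than approached. Covariance construction is
O(n²) in memory; above `getOption("phyrange.max_tips", 5000)` taxa the
package raises an error advising pruning instead of attempting the
allocation.

**Log-OLS.** Natural logarithms throughout: the percentage-difference
effect size `100 (e^b - 1)` requires them, and any display in log10 is
presentation only. Non-positive responses are an error listing the
offenders; the pipeline filters them out with a logged count before
fitting.

**Quasi-Poisson.** Log-link Poisson score equations by IRLS (relative
tolerance 1e-10, at most 100 iterations), dispersion as the Pearson
statistic over `n - p`, standard errors inflated by its square root. The
botanical-country metric needs this: with most species native to a single
unit the counts cannot be transformed to approximate normality, and they
are overdispersed relative to Poisson. PGLS is never paired with this
metric — a quasi-likelihood has no density to combine with the
phylogenetic covariance, and the pipeline enforces the exclusion.

**Effect sizes and intervals.** Wald intervals on the coefficient scale,
transformed: `100 (e^{b ± 1.959964 se} - 1)`. Bootstrap intervals were
considered and rejected: at the sample sizes involved the Wald intervals
are accurate, and the multi-tree layer already adds a resampling-like
spread.

**Multiple trees.** Fits are repeated per tree; the summary reports the
coefficient mean and the *standard deviation of the tree-wise estimates*.
That spread is a between-tree uncertainty, deliberately not divided by
the square root of the number of trees: the trees are not independent
samples of anything, and the spread answers "how much does phylogenetic
uncertainty move the estimate", not "how precise is the mean". Within
grouped analyses (e.g. per family) lambda is re-estimated per group
rather than fixed globally — phylogenetic signal in residuals is not
plausibly constant across clades.

## Rarity

`rare_by_eoo`: EOO strictly below 20,000 km², the criterion B1 area
threshold for a "vulnerable" listing. `rare_by_specimens`: five or fewer
specimens. Species missing a metric are excluded from that metric's
denominator — proportions are "of the species for which the metric could
be estimated", which is how such figures are meaningfully quoted — and
both flags are `NA` rather than false for missing metrics so the
distinction survives into output files.

## Sensitivity subsets

`tropical_only` keeps species whose native-region centroid latitudes
average within ±23.436 degrees (the tropic circles; the simple mean is
used rather than an area-weighted one — centroids are the only
geometry the atlas guarantees). `exclude_oceanic_islands` drops species
with *any* oceanic-island native region by default; an `"all"` mode
requiring every region to be an island is available, since "occurring on
oceanic islands" is genuinely ambiguous for partial islanders.

## The synthetic-data generator

The generator exists so that every stage has ground truth; its defaults
are the package's study conditions.

- **Phylogeny**: forward Yule process (birth rate 1), chosen over an
  n-conditioned reconstruction because its depth has the closed form
  `sum_{k=2..n} 1/(k b)` that the tests check. 200 species by default —
  large enough for the regression layer's asymptotics to be visible,
  small enough that a replicate fits in milliseconds.
- **Lifeform**: two-state Markov evolution (rates 0.3/0.3) from a
  stationary root, giving the phylogenetically clustered epiphytism seen
  in real floras. The defaults give a roughly balanced trait, which
  maximises regression power; the real epiphyte fraction (~8% of
  angiosperms) would only shrink power without changing any tested
  property.
- **Log range**: `y = alpha + beta * 1[epiphyte] + eps`, with `eps`
  multivariate normal under the lambda-transformed Brownian covariance —
  exactly the model PGLS fits, so recovery is a well-posed question.
  Defaults: `alpha = log(3000)` (a typical EOO, in km², for species
  restricted to four or fewer botanical countries), `beta = log(1.5)`,
  `lambda = 0.8`, `sigma2 = 1`.
- **Occurrences**: clean georeferenced records are drawn uniformly in a
  disc centred in the species' native region, with the disc inflated by
  the expected convex-hull coverage of `n` uniform points
  (`1 - 3.08 n^{-2/3}`, an empirical fit) so the hull area matches the
  species' target EOO within ~15% for 30+ points. Record counts are
  negative-binomial (size 1.2) with mean scaling as the 0.4 power of
  relative range size — collections are strongly skewed and
  range-dependent, which is what makes specimen count a usable range
  proxy. Botanical-country counts are drawn with 56% single-country
  species and a small widespread tail, matching the prevalence pattern
  that motivates the quasi-Poisson model. Violations are planted at most
  one per record, each class aimed at exactly one filter, so removal
  precision and recall are well-defined and must be 1.0.
- **Scenarios**: `baseline` as above; `null_effect` sets `beta = 0` (for
  coverage checks); `confounded_clades` joins two shallow Yule clades by
  long stem branches (default 1000 time units, `sigma2 = 0.2`,
  `lambda = 1`) and assigns epiphyte-rich status (P = 0.9 vs 0.1) to the
  clade whose realised deep-branch Brownian displacement is negative.
  The long stems emulate anciently diverged, epiphyte-rich lineages —
  the orchid situation — and make the clade-level displacement large
  relative to within-clade variation, so the ordinary/phylogenetic sign
  flip is a reliable property of the scenario rather than a fortunate
  draw.
- **Tree sets**: imputation uncertainty is emulated by collapsing short
  internal branches into polytomies and resolving them at random, with
  the new branches given small lengths borrowed from their children so
  tip depths are preserved. Zero-length resolutions would be
  covariance-identical and make between-tree spread trivially zero.

What the generator does **not** emulate: real botanical-country geometry
(regions are rectangles on a toy globe), the empirical distribution of
GBIF record counts and their spatial biases, taxonomic name changes,
extinction in the tree (pure birth only), and hemi-epiphytes. Passing
tests therefore demonstrate that the machinery is correct under its own
model, not that any particular empirical dataset is clean or that real
effect sizes take any particular value.

## Numerical choices and degenerate inputs

- Longitudes are normalised to (-180, 180]; latitudes are never wrapped —
  an out-of-range latitude nulls the coordinate pair and is logged.
- Zero/equality tests on coordinates are exact on parsed values.
- Cholesky factorisation everywhere a covariance is inverted or sampled;
  singular covariances and rank-deficient designs are named errors.
- The quasi-Poisson fitter flags exact zero dispersion (all residuals
  zero) with a warning and reports diverging linear predictors (a group
  of all-zero counts) as errors rather than returning huge finite
  estimates.
- Deduplication and thinning keep the first record in input order;
  cleaning output preserves input order, and a second pass removes
  nothing (idempotence is asserted in the tests).
- Range tables round-trip through CSV with integers bit-exact and EOO to
  at least 12 significant digits (written with 15).

## Problem sizes

The test suite validates the GLS layer against a brute-force oracle on
200 random trees of up to 10 tips; parameter recovery and the sign
reversal on 50 scenario replicates of 200 tips each; null coverage on 100
replicates; EOO invariants on 1000 random point sets; and the cleaning
pipeline on generator fixtures of a dozen species. These sizes were
chosen so the whole suite runs in about a minute on a laptop while
keeping Monte-Carlo error well below the asserted margins; the same
logic, not any statistical limitation, sets the scenario sizes in
`scripts/acceptance.R`.

## Known limitations

- No name resolution or fuzzy matching: species identifiers must already
  agree between checklist, occurrences and trees (underscores and spaces
  are interconverted when matching tips).
- Polygon holes and multi-ring interiors are not supported by the atlas.
- No alternative correlation structures (Ornstein-Uhlenbeck), no
  phylogenetic model for count responses, no area-of-occupancy metric,
  and no Red List subcriteria beyond the B1 area threshold.
- PGLS drops species absent from a given tree from that tree's fit only;
  if many species are missing, the ordinary and phylogenetic models are
  no longer fit to comparable datasets and the effect comparison should
  be interpreted accordingly (the pipeline reports the counts).
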