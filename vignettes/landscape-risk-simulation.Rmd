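---
title: "Landscape ecological risk and patch-generating land-use simulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape ecological risk and patch-generating land-use simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lersim)
```

This vignette is the package's own account of its models: what is
computed, which conventions the numbers depend on, which parts of the
procedure are reconstructions of verbally described mechanisms, and what
the synthetic tests do and do not demonstrate.

## The risk model

The landscape ecological risk index treats each land-use class as a
carrier of risk proportional to how disturbed its pattern is and how
vulnerable its ecosystem is.  Within a scope with total area $A$, class
$i$ with $n_i$ patches, area $A_i$ and total perimeter $P_i$ gets

$$C_i = \frac{n_i}{A_i}, \qquad
  N_i = \frac{1}{2}\sqrt{\frac{n_i}{A}}\cdot\frac{A}{A_i}, \qquad
  F_i = \frac{2\ln(P_i/4)}{\ln A_i},$$

$$E_i = a\,C_i + b\,N_i + c\,F_i, \qquad R_i = E_i V_i, \qquad
  \mathrm{ERI}_k = \sum_i \frac{A_{ki}}{A_k} R_i .$$

**Unit conventions matter and are not interchangeable.**  $C_i$ and
$N_i$ use areas in hectares; the reference values shipped with the
package (`cma_pattern_table()`) only reproduce under hectares.  $F_i$
uses perimeter in meters and area in square meters; the source tables do
not print perimeters, so $F_i$ cannot be validated against them and its
unit convention is a package decision, checked instead against a
brute-force patch oracle.  $F_i$ uses class-total perimeter and area
(the indices are defined per type, not per patch); a square patch gives
exactly $F_i = 1$ under this form, and values are clipped to $[1, 2]$
with a warning.

**Vulnerability normalization.**  The ranks (water 5,
cultivated/orchard 4, grassland 3, forest 2, construction 1) are
normalized by their sum by default ($V_i = v_i / \sum_j v_j$, so
$\sum V_i = 1$); division by the maximum rank is available as
`v_method = "max"`.  Only "normalization" is conventionally specified
for this step, so the choice is config-exposed: grade boundaries shift
with it, and comparisons across runs must hold it fixed.

**Absent classes.**  A class with zero area in a scope has no defined
metrics; its values propagate as `NA` and it contributes nothing to the
unit's ERI.  Mapping absent metrics to zero instead would silently drag
unit ERI toward zero in class-poor units.

**Patch delineation.**  Patches are connected components of equal-class
cells on the cell-adjacency graph.  Default connectivity is 8 (diagonal
neighbors join a patch), matching common landscape-metrics practice;
4-connectivity is exposed because the convention is rarely stated by
sources.  Perimeter counts cardinal cell edges against a different
class, the nodata mask, or the grid boundary — i.e. boundary edges
count, the usual raster default.  Both conventions are cross-checked
against an independent flood-fill oracle in the test suite.

## Evaluation units, kriging, grading

Units are squares (default 3 km, snapped to whole cells) tiling the
bounding box from the top-left corner; units with less than half their
nominal area inside the mask are dropped (the threshold is an argument —
edge-unit retention is a judgment call, and published unit counts
suggest partial units are usually kept).  Two metric scopes exist:
`mode = "unit"` recomputes $C_i, N_i, F_i$ inside each unit
(vulnerability stays global) and is the default for mapping spatial
heterogeneity; `mode = "landscape"` uses one global $R_i$ per class, so
a single degenerate unit covering everything reproduces the
whole-landscape ERI exactly.

Unit values are interpolated by ordinary kriging with a spherical
variogram.  The partial sill and range are fitted to the binned
empirical semivariogram by weighted least squares (Nelder–Mead on log
parameters); the nugget defaults to 0, which makes the interpolator
exact at unit centroids — a property the tests assert to $10^{-6}$.
Duplicate sample locations are rejected rather than jittered.  A
constant field short-circuits to the constant (the variogram is
degenerate there).  Prediction is chunked (5000 cells per solve) to
bound memory.

Grades come from Jenks natural breaks: the exact Fisher dynamic program
minimizing within-class sum of squares, $O(kn^2)$ with prefix sums.
Inputs above 2000 values are represented by evenly spaced order
statistics before the DP — for the smooth interpolated fields being
classified this changes breaks negligibly, and the exact DP is always
used below the threshold (tests compare it against exhaustive search).
A value exactly on a boundary belongs to the lower grade.  Published
grade thresholds for the CMA are shipped (`cma_risk_breaks()`) for runs
that need frozen, comparable breaks.

## LEAS: learning growth probabilities

Expansion of class $k$ between two epochs is the cell set that is $k$
in the later epoch but not in the earlier one.  "Non-uniform" sampling
is implemented as stratified sampling: all expansion cells are eligible
positives, negatives are drawn uniformly from non-expansion cells, and
the overall rate (default 1% of unmasked cells per class, split evenly
between labels where possible) controls the sample size.  A probability
random forest (ranger, 100 trees, default mtry, fixed seed, one thread
for bit-reproducibility) is fitted per class and evaluated at every
unmasked cell; impurity importances are reported.  A class with no
observed expansion cannot be fitted: the default is an explicit error
naming the class, while the pipeline functions opt into a zero surface
with a message, which simply means the CA will not seed that class
anywhere its neighborhood effect is zero.

## CARS: allocating demand

Each iteration, for every cell $i$ and class $k$:

* the neighborhood effect $\Omega_{i,k}$ is the cover ratio of $k$ in
  the (default $3\times3$) window excluding the center, scaled by the
  class's neighborhood weight (construction 1, forest 0.8, cultivated
  and grassland 0.5, water 0.1; orchard is set to 0.5 — between
  cultivated and forest — because no published weight exists for it);
* the overall probability is
  $P_{i,k}\,\Omega_{i,k}\,D_k$ in general, and
  $P_{i,k}\,(r\,\mu_k)\,D_k$ where $\Omega_{i,k}=0$ and the
  Monte-Carlo draw $r < P_{i,k}$ — the patch-seeding branch
  ($\mu_k$ defaults to 0.1);
* a candidate class is drawn per cell by roulette wheel over the
  overall probabilities, and the cell converts only if the candidate's
  growth probability exceeds the decaying threshold
  $\tau = \delta^d r_1$ ($\delta = 0.5$; $r_1 \sim U(0.9, 1.1)$, a
  unit-mean perturbation whose width is a package choice), the
  transition matrix allows the conversion, and the cell is not
  restricted.

Two mechanisms are reconstructions of verbally described components and
are flagged as such:

* **Inertia $D_k$.**  Only its role is conventionally described (it
  adapts allocation pressure to the gap between current area and
  demand).  Here $D_k$ stays 1 while a class's absolute gap shrinks, is
  multiplied by the capped gap ratio when the gap widens (upward for
  under-supply, downward for over-supply, cap 2, clamped to
  $[0.01, 100]$), is nudged by $\times 1.05^{\pm 1}$ when a nonzero gap
  stalls, and resets to 1 at demand.
* **Demand guard.**  A cell may convert to $c$ only while $c$ is below
  its demand and the donor class is above its own.  Per-class areas
  therefore approach demand monotonically, total area is conserved by
  construction, and convergence is declared when every gap is within
  0.1% of the landscape cell count (configurable).  Within an
  iteration, proposals are processed in random order and capped per
  donor and per target so neither side overshoots.

The decay counter $d$ advances whenever an iteration improves the total
absolute gap by less than `Step` (default 0.1% of cells), so stalled
runs see $\tau$ fall geometrically until low-probability conversions
become admissible; $\tau$ is floored at $10^{-6}$ to stay positive.
The Monte-Carlo draw $r$ is made once per cell per iteration and shared
across candidate classes.  All randomness flows from one seed; repeated
runs are bit-identical, different seeds differ in patch geometry but
meet the same demand.

## Scenarios and demand

Scenarios are multiplier tables on conversions plus restricted zones:
EDS multiplies all conversions into construction by 1.4; EPS halves
conversions out of forest, raises conversions into forest by 1.3,
cuts non-forest conversions into construction by 0.8, and freezes water
cells; NDS changes nothing.  Multipliers act on the learned growth
surfaces (at cells whose current class matches the rule source), then
re-clip to $[0,1]$.  When custom rules overlap, the default is that a
later rule overrides an earlier one — ordering rules from general to
specific gives most-specific-wins — with `combine = "compose"` to
multiply instead; the three shipped scenarios have no overlapping
rules.  Demand is projected by a one-step Markov chain estimated from
the two observed epochs (equal-interval assumption), and scenario
multipliers are also applied to the off-diagonal transition rates
(rows kept stochastic via the diagonal) so that policy shifts demand as
well as allocation — a package decision, since the provenance of
published scenario demands is not stated.

## The synthetic generator

`generate_landscape()` builds categorical maps by seeded region growing:
each class gets a seed count (default contrast: many seeds for
cultivated/grassland, few for forest) and classes grow from their seeds
into unassigned cells, in random class order with randomized frontier
bites, until integer cell budgets — by default proportional to the
published 2000 CMA class shares — are met exactly.  Enclosed classes
reseed, so realized patch counts exceed seed counts for large classes.
This was chosen over thresholded Gaussian fields because it gives direct
per-class control of patch-size contrast, which the tests rely on
(forest must form the largest coherent patches).  Drivers are smooth
box-blurred Gaussian fields (elevation; slope as its gradient),
distances to random point/line features (towns, roads, rivers), and
town-distance-decaying population/GDP surfaces.  `generate_change()`
converts a fixed budget of cells per rule with probability logistic in a
standardized driver, recording every conversion as ground truth.

What the generator does *not* emulate: real terrain correlation between
land use and elevation, anisotropic patch shapes, multi-date driver
dynamics, or the actual geometry of any real landscape.  Passing tests
demonstrate that the machinery recovers programmed structure under the
stated conditions, not that it would reproduce any particular region's
published risk values — reproducing those requires the original rasters,
which are not redistributable here.

## Problem sizes and numerical choices in the tests

The default synthetic fixture is 200×200 cells at 30 m (36 km²), small
enough for a full LEAS + CARS + risk run in seconds.  The
driver-recovery experiment runs 20 seeds at this full fixture size
because the 1% sampling rate is the study condition, and at smaller
grids it yields sample sizes (tens of cells) whose importance rankings
are dominated by sampling noise rather than by the signal being tested.
Oracle-equivalence checks use 50 random grids up to 30×30 against a
recursive flood-fill implementation; Jenks is compared with exhaustive
search up to $n = 25$, $k = 4$.  Six cells of the shipped
pattern-index reference table are internally inconsistent at the fourth
decimal (their printed components round to a value one digit away from
the printed composite); the tests document and exclude exactly those
cells rather than loosening the tolerance for the rest.

## Known limitations

* Kriging offers only the spherical model with an automatic fit; no
  anisotropy, no model selection.
* The CA's inertia rule and demand guard are reconstructions (above);
  other choices could allocate the same demand with different patch
  geometry.
* Per-unit metric mode recomputes patches inside unit windows, so
  patches straddling unit edges are split — a known scale effect of
  windowed landscape metrics.
* TIFF input is plain single-band imagery (no georeference): the cell
  size must be supplied; ESRI ASCII grids are the primary format.
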