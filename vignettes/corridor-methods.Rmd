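---
title: "Models and methods behind corridorscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind corridorscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Long-distance terrestrial migrations persist only where animals can cross
working landscapes of fences, roads, wells and croplands. Planning where to
spend conservation effort (fence conversion, easements) requires mapping
*migration corridors*: the subset of the landscape that carries most of the
seasonal movement. corridorscope implements a full comparison of the two
standard modelling axes used for this purpose:

* **habitat suitability**: a presence-only maximum-entropy model (Maxent-style)
  fitted to pooled migration GPS fixes, versus an expert-judgment model built
  with the Analytic Hierarchy Process (AHP);
* **connectivity**: least-cost corridor mapping (cost-distance accumulation)
  versus circuit-theory current flow,

crossed over two migration seasons and five corridor-width thresholds
(1/5/10/15/20% most traversable habitat), scored by the percentage of
telemetry fixes each corridor captures per unit of study area, and condensed
into a tiered priority overlay (Tier 1 = union of the seasonal 1% corridors,
Tier 2 = intersection of the 5% corridors, Tier 3 = intersection of the 10%
corridors).

Because the original GIS layers, expert surveys and collar data are not
released, the package ships a first-class synthetic generator that emulates
the study system, and every claim a test makes is made against that stated
world or against an independent numerical oracle.

# The maximum-entropy model

Over a background sample of cells $B$ with feature vectors $f(x)$ the model
is the Gibbs distribution $q(x) \propto \exp(\lambda \cdot f(x))$ maximizing

$$J(\lambda) = \frac{1}{m}\sum_{i=1}^{m} \lambda \cdot f(x_i) - \log Z -
\sum_j \beta_j |\lambda_j|,$$

the L1-regularized mean log-density of the $m$ presence cells. Features are
linear and quadratic terms of standardized continuous covariates plus one
indicator per category of categorical covariates; hinge/threshold features
are deliberately out of scope to keep the convex core small and
oracle-checkable. Optimization is greedy coordinate ascent: each iteration
scores every feature's soft-threshold (prox) step under a quadratic gain
model and applies the best one, with a damped safeguard so the objective
never decreases. The per-iteration gains, credited to the covariate owning
the updated feature, are the variable-contribution table; this sequential
credit assignment is why greedy selection is used rather than cyclic sweeps
(sweeps systematically over-credit whichever covariate happens to come first
in the stack).

At convergence the KKT conditions give the box constraints
$|E_q[f_j] - \bar f_j| \le \beta_j$, which the tests assert directly.

**Regularization.** `beta` (default 0.5) is a multiplier: the per-feature
weight is $\beta\, s_j/\sqrt{m}$ with $s_j$ the background standard
deviation. A flat absolute weight of 0.5 on standardized features would
zero every coefficient at realistic sample sizes (every presence-background
mean gap is far below 0.5), so the sample-size scaling used by the
published Maxent implementations is adopted instead.

**Outputs.** `raw` sums to 1 over the background; `log` is its natural log
(the basis of the resistance transform); `logistic` is
$\mathrm{plogis}(H + \log q)$ with $H$ the entropy of $q$, so a
no-information model scores 0.5 everywhere. The resistance surface is
$1 - \mathrm{rescale}_{01}(\log q)$ mapped onto $[0.01, 1]$; the floor
keeps graph edge weights strictly positive.

# The AHP model

Experts compare the seven covariates pairwise on the 1–9 scale, and the
categories within each covariate likewise. Weights are the normalized
principal right eigenvector of each reciprocal matrix (power iteration,
tolerance 1e-10), checked against a dense eigendecomposition in the tests.
Consistency is diagnosed with $CI = (\lambda_{max}-n)/(n-1)$ and
$CR = CI/RI(n)$ using the standard random-index table; $CR > 0.1$ is
flagged but not rejected (whether the study screened surveys is unknown, so
all surveys are kept by default). Multiple surveys aggregate by element-wise
geometric mean (aggregation of individual judgments), which preserves
reciprocity exactly. Category weights are rescaled so the best category of
each variable scores 1; the surface is the weighted linear combination
$\sum_v w_v\, s_v(\mathrm{cat}_v(x)) \in [0,1]$, inverted and mapped onto
$[0.01, 1]$ as a cost surface.

The synthetic truth model is expressed in exactly this scoring form, so
"generator scored through the AHP path equals the generator's own surface"
is an identity the tests check bit-for-bit.

# Connectivity engines

Both engines see the same 8-connected grid graph with the de facto GIS edge
convention: the weight between neighbours $a,b$ is
$\tfrac{1}{2}(c_a + c_b)\,d$, $d$ being the cell size (orthogonal) or
$\sqrt 2$ times it (diagonal).

**Least-cost corridors.** Multi-source Dijkstra gives the accumulated cost
distance from the source patch and from the destination patches (their
union acting as one source set, equivalent to the cellwise minimum over
per-destination solves); the corridor surface is the sum, whose minimum is
the patch-to-patch least-cost-path cost. Path backtracking breaks ties
toward the smallest linear cell index, so returned paths are deterministic.

**Circuit theory.** The resistance raster becomes a resistor network with
edge conductance $1/(\tfrac{1}{2}(r_a+r_b)d)$ — the same endpoint-mean rule
as the cost graph, one convention shared across both engines so the
surfaces are commensurate. Habitat patches contract to supernodes (zero
internal resistance). Grounding one focal node and injecting unit current
at the other reduces Kirchhoff's laws to a sparse reduced-Laplacian solve
(`Matrix`); per-edge currents follow from Ohm's law and the source voltage
is the effective resistance. The per-cell current map is half the sum of
absolute incident-edge currents; focal cells carry the injected current.
Circuit solves run by default on a factor-3 aggregated grid, mirroring the
field practice of coarsening (30 m to 90 m) for tractability; coarse cells
claimed by two patches after aggregation stay with the first patch so
supernodes remain disjoint.

**Slicing.** Corridor masks keep the lowest-cost (or highest-current) $p\%$
of valid cells — the minimal superset including ties — or, optionally, a
value-range basis (`min + (p/100)(max-min)`). Both bases are implemented
because the study's reported corridor areas imply its GIS toolbox did not
use an area percentile of the analysis extent; area-percentile is the
default for determinism, and every mask records its basis and threshold in
a provenance attribute. Percentile slices nest in $p$ by construction;
where current values tie (focal cells all carry the injected unit),
consecutive masks can coincide, so nesting is asserted as set inclusion.

# Patch identification

Suitability is thresholded at the equal-sensitivity/equal-specificity point
of presence versus background scores; 8-connected components of the
suitable mask become candidate patches. The source patch is the component
maximally overlapping the collaring-area hint; destinations are components
overlapping the destination hints, ranked by presence density. Where the
study isolated patches by hand, an automated stand-in is needed for the
case where one connected blob of good habitat swallows several hints: the
threshold is raised in steps of 2.5% of the score range until the source
separates from the destinations and the destination hints resolve to
distinct components.

# Migration preparation

Daily displacement is the sum of step lengths starting on each calendar
day. The study identified migration windows visually; the package codifies
a reproducible rule: a day is migratory when its displacement exceeds
$\theta = \max(k\,\mathrm{median}, \mathrm{floor})$, and the window is the
longest contiguous run of such days (earliest on ties). With the reported
daily means — 6,973 m during migration against 4,827 m otherwise — a
multiplier of $k = 2$ would put $\theta$ *above* the migratory mean, so the
default is $k = 1.25$ with a 5,000 m floor: roughly 25% above a typical
day, comfortably below migration. Both knobs are exposed.

Long-distance migrants are individuals whose pre- and post-window range
centroids are more than 50 km apart (strict inequality); the opposite
season's period bounds the comparison so the return migration cannot
contaminate the centroids. Pooled seasonal presence sets are the union of
within-window fixes of all migrants, stopovers included.

# The synthetic world

Defaults state the studied system; they are conditions, not dials.

* **Grid**: 120 x 120 cells at 900 m (~108 km square). The study analysed at
  30 m, but >50 km migrations cannot fit a desk-scale grid at 30 m; the
  coarser cell is the one deliberate rescaling, and distance-attribute bin
  edges are scaled with it (distance-to-water keeps the published
  1/10 km edges; wells and roads use 1.5/8 km and 1.5/5 km).
* **Land cover**: quantile-thresholded smoothed Gaussian fields hit 56%
  grassland and 26% agriculture by construction (water, development,
  wetlands, pasture share the remainder).
* **Patches**: one southern source (the collaring area, with the well field
  clustered around it) and three northern destinations, >50 km away.
* **Seasonal NDVI**: spans the full [0, 1] range so all four published NDVI
  attribute bins are populated; spring greens up around the destination
  patches, fall greenness concentrates near water — the seasonal contrast
  the study reported (spring presence tracked high NDVI, fall presence
  tracked water). The spring truth model weights NDVI highest (0.40), the
  fall model distance-to-water (0.42), mirroring the reported contribution
  rankings, and NDVI carries the largest realized variance share of the
  spring truth surface so contribution-recovery tests are well posed.
* **Fences**: along internal parcel boundaries separating ownership classes
  and offset along one side of each maintained road; rasterized one cell
  wide; ground-truth points (default 1,788) are jittered on-fence samples
  plus a 15% contamination fraction standing in for unmapped fences, which
  puts modelled accuracy in the reported >82% regime.
* **Telemetry**: 42 individuals, 17 spring and 18 fall migrants, 2-hourly
  fixes, 25-day windows (~300 window fixes per migrant, pooling to ~5,100
  spring points). Movement is a step-length/heading walk: step lengths sit
  tightly around the daily budget (6,973 m migrating, 4,827 m otherwise, as
  published) while *directional* noise supplies tortuosity, adapted each
  step so the animal arrives as its window closes; candidate headings are
  scored against the true suitability surface so routes prefer good
  habitat. Putting the noise in heading rather than position keeps the
  daily-displacement variance a few percent, which is what makes threshold
  window detection reliable. At `noise = 0` the walk collapses to a
  straight line at uniform pace — net displacement equals patch separation,
  so migrant classification is exact, but daily displacement drops below
  the detection threshold; the zero-noise recovery test classifies from
  seasonal-period centroids, by design.
* **Presence sampling** (`gen_presences`): cells drawn with probability
  $\propto \exp(\text{effect}\cdot z)$ of standardized true suitability;
  the default effect of 1 places held-out AUC of a well-specified model
  near 0.66–0.70, the regime reported for the real data.

What a green test does *not* establish: the generator has no fix dropouts,
no collar failure, no interannual variation (the study pooled two years),
no partial migration ambiguity, smooth stationary covariate fields rather
than real hydrography/cadastre, and fences with uniform permeability. The
capture percentages it produces are internally consistent but not
comparable to the study's (its corridors captured ~71% of spring points in
~25% of the study area; the synthetic world's geometry differs).

# Numerical choices

* Bin edges are left-closed/right-open; a value on an edge falls upward.
* Distances are Euclidean between cell centers (exact two-pass distance
  transform in C++).
* Maxent: epsilon floor 1e-12 before the log transform; convergence when
  KKT constraints hold to 1e-8 and no step is worth more than 1e-8;
  presences deduplicated to one per cell by the pipeline (configurable).
* Resistance floor r_min = 0.01, shared by both HSM paths.
* Power iteration tolerance 1e-10; circuit solves direct sparse.
* Ties: earliest window; lowest equal-sens/spec threshold; smallest-index
  predecessor on equal-cost paths; smallest category code on majority
  resampling ties.
* ESRI ASCII and a minimal single-band float64 GeoTIFF are written/read
  natively (no GeoTIFF-capable R package exists in the target environment);
  the GeoTIFF subset was validated against an independent TIFF reader.

# Known limitations

Single-year world; no projection support (planar meters only); corridor
evaluation mixes grids across engines (circuit corridors live on the
aggregated grid — each record's area denominator is its own grid's valid
cells); no hinge features; no fence permeability attributes; the CLI runs
the pipeline end to end rather than resuming individual stages (each stage
is an exported R function).
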