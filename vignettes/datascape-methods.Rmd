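---
title: "The datascape: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The datascape: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(datascaper)
```

## The model

A dataset $X = \{x_i\}$ of $n$ points in $d$ ambient dimensions is assumed
to be sampled — possibly unevenly — from an unknown lower-dimensional space
with a shape of its own: curved, possibly disconnected, possibly with holes.
The datascape abstracts that space with two coupled structures built from a
single parameter $k$ and an ambient metric $d_A$ (Euclidean by default).

**The neighborhood graph.** Each point is linked to its $k$ nearest points
under $d_A$ (its *natural* neighbors). Because nearest-neighborhood is not
a symmetric relation — an isolated point may elect a neighbor in a dense
region that does not reciprocate — every one-directional link is kept and
the missing direction is added: the target gains the source as an
*enforced* neighbor. The result is an undirected graph whose edge weights
are the ambient distances $\omega_{ij} = d_A(x_i, x_j)$. If the graph
splits into $m$ components, the closest cross pair of points between each
pair of components defines a candidate *connecting* edge, and a minimum
spanning tree over the component meta-graph selects the subset that
reconnects everything with the smallest total added weight. Connecting
edges are tagged: they exist so that geodesic distances are finite, and
they are excluded whenever the shape of the data matters (hull
construction, risk neighborhoods, the distance-error experiment).

**The geodesic metric.** The distance between two points is the minimum
cumulative edge weight over graph paths (Dijkstra). Because edges only
join ambient-space neighbors, this distance follows the shape of the data
rather than cutting through empty regions: on a connected graph it is a
true metric that never undercuts the ambient distance, and it collapses to
the ambient metric in the complete-graph limit $k = n - 1$.

**The shape estimate.** Each point contributes the convex hull of itself
and its (natural and enforced) graph neighbors; the union of these local
hulls is the estimated support of the data. A union of small convex pieces
is a good-cover-style construction: unlike the single global convex hull
of $X$, it preserves holes and cavities. A query point is *inside* the
datascape iff it lies in at least one local hull. The *extreme points* are
those dataset points that are hull vertices of every local hull containing
them; they trace the boundary surface of the estimate. The boundary search
is restricted to the dataset points themselves rather than the continuum
surface — the continuum definition quantifies over every point of the
shape and is not computable as stated, and the point-restricted version is
what the downstream scores need.

## Parameters that matter

- `k` (no default; required). The scale of the abstraction, in points. Too
  small and the graph fragments or misses topological features; too large
  and edges short-circuit across cavities, degrading both geodesics and
  the shape. `k_scan()` (components and circuit rank per `k`) and
  `circle_error_curve()` explore the trade-off; the choice belongs to the
  analyst and depends on the question. Values `>= n` are clamped to
  `n - 1` with a warning so small fixtures still work.
- `metric` (default `"euclidean"`). Any non-negative symmetric function of
  two coordinate vectors is accepted; it is used for neighbor selection,
  edge weights, and out-of-sample insertion. Euclidean is the default
  because it is the standard choice for manifold-learning neighbor graphs
  and the metric under which all package experiments run.
- `tol` (default `1e-9`, relative). A point within `tol` times the hull
  diameter of a hull's surface counts as inside. The boundary convention
  is inclusive by necessity: a hull vertex must count as belonging to its
  own hull for the extreme-point logic to be well defined.
- `connect` (default `TRUE`). Whether to add connecting edges. Distance
  queries default to using them; the circle distance-error experiment
  forces them off because an infinite distance between components is part
  of what that experiment measures.

## Numerical choices

**Hull membership.** No convex-hull or linear-programming package is
available in the package's dependency footprint, so membership is decided
by a compiled Lawson–Hanson non-negative least-squares solver written for
this package: the distance from a query $q$ to
$\mathrm{conv}(V)$ is the minimum of $\lVert V^\top \lambda - q \rVert$
over the simplex, solved through an augmented system that carries the
sum-to-one constraint as a heavily weighted row. For interior points the
attainable residual is exactly zero, so the test is accurate to machine
precision; for exterior points the renormalized combination gives a tight
upper bound on the true distance. Inputs are centered and scaled before
solving. Full-dimensional two-dimensional hulls additionally store facet
half-spaces (from `grDevices::chull`) and use the cheaper facet test; the
two routes are asserted to agree in the test suite, and an independent
LP-feasibility oracle (pracma's simplex) cross-checks membership on
hundreds of random cases.

**Hull vertices.** A point of a hull's input set is a vertex iff its
distance to the hull of the remaining points exceeds the tolerance — one
NNLS solve per input point. Exact duplicates are removed first (two
coincident points would otherwise eliminate each other).

**Degenerate hulls.** When a neighborhood spans an affine subspace of
dimension below $d$ (e.g. `k <= d`, or collinear neighbors), the hull is
flagged degenerate and membership means lying on that lower-dimensional
piece within tolerance; the NNLS route handles this without special
casing, since distance-to-hull is well defined regardless of affine rank.

**Tie-breaking.** Equal distances during neighbor selection (and
out-of-sample insertion) are broken by ascending row index, which makes
graph construction fully deterministic. Among equal-length geodesic paths
the reported path is the one igraph's Dijkstra yields; for a fixed build
this is reproducible, but no lexicographic minimality among ties is
claimed — the length, which is what the package's guarantees concern, is
unique.

**Disconnection.** An unreachable geodesic query returns an
infinite-length result, never an error; the distance-error experiment
relies on this sentinel.

**Duplicates.** Duplicate points are permitted (zero-weight edges, mutual
nearest neighbors); `drop_duplicates = TRUE` removes them at build time
for callers who prefer the cleaned dataset.

## Sampling inside the shape

`sample_datascape()` draws, per hull, convex combinations of the hull
vertices with flat Dirichlet weights — uniform on the vertex-weight
simplex. This is rejection-free and dimension-independent, and every
sample is inside its source hull by construction. It is *not* uniform over
hull volume: density is biased toward vertex-dense regions. The package
documents this bias rather than correcting it, because volume-uniform
sampling of a hull union would require per-hull volume computation, which
is deliberately out of scope.

## Scores, prediction and trajectories

With binary labels, each point's risk score is the fraction of positive
labels among its graph neighbors (self excluded, connecting neighbors
excluded — a connecting edge records reachability, not similarity). An
out-of-sample point is scored by inserting it: it gains edges to its $k$
nearest dataset points and takes the label ratio of that neighborhood,
which is exactly a $k$-nearest-neighbor vote; the test suite asserts that
equivalence against an independently coded voter. Trajectories insert each
time-indexed state, score it, and measure the geodesic between the first
and last states on a graph augmented with both; when several states are
inserted together they may select each other as neighbors, so a constant
trajectory yields a zero-length geodesic through a zero-weight edge.
`cv_risk_auc()` benchmarks the construction as an unsupervised classifier
with label-stratified folds, rebuilding the graph on each training fold
and scoring held-out points by insertion.

AUC is computed by the Mann–Whitney rank identity with midranks for ties.

## What the synthetic generators emulate

- `sim_sinusoid()` — a one-dimensional curve in 3-d thickened by bounded
  uniform noise (`x ~ U(0, 2*pi)`, `y = cos(x)`, `z = cos(x - 0.5)`, with
  noise amplitudes 1, 0.3, 0.3): tests boundary detection and in-shape
  sampling on a curved, noisy band. Defaults to `n = 1000` and `k = 10` in
  the experiments.
- `sim_torus()` — the standard torus surface (`R = 2`, `r = 1`), sampled
  uniformly in parameter space (not area-corrected; the inner tube is
  slightly oversampled, which none of the experiments is sensitive to).
- `sim_circle()` — 100 points on the unit circle by default, with latent
  angles retained so geodesics can be compared against exact arc lengths.
- `sim_annulus()` — a ring with a central cavity: the motivating contrast
  between the hull union (cavity preserved) and a global hull (cavity
  swallowed).
- `sim_cohort()` — two unit-variance Gaussian clouds separated by
  `separation` along the first axis, optional label flipping. A separation
  of 2 (about two within-class standard deviations) is used as the
  "moderate overlap" benchmark condition; 0 is the null and 6 the
  separable limit. It stands in for a binary-outcome clinical cohort; it
  does not emulate longitudinal structure, missingness, or mixed-type
  features of real clinical data, so classifier results on it demonstrate
  correctness of the scoring machinery, not clinical performance.

What passing these tests shows — and does not show — about real data: the
generators produce low-dimensional, moderately sized, fully numeric,
complete datasets. Heavy-tailed noise, high ambient dimension (where local
hulls of `k` points are almost always degenerate), missing values
(explicitly rejected, never imputed) and categorical features are outside
what the test evidence covers.

## The distance-error experiment

For the circle, the error of a pair is
$\min(1, |d_G - d_{\mathrm{arc}}| / \pi)$ and disconnected pairs score 1.
The standardization is a modelling choice of this package: the reference
behavior fixes the disconnected-pair error at the maximum, 1, but leaves
the connected-pair formula open; dividing by $\pi$ (the largest possible
arc distance) makes 1 a true maximum and puts the whole curve on $[0,1]$.
The characteristic curve shape — maximal error while fragmented, a sharp
drop at one component, a minimum once the circle's cycle appears
(typically `k = 6` at `n = 100`), and a slow rise toward the chord-limit
error $(\pi^2/2 - 4)/\pi^2 \approx 0.095$ at `k = n - 1` — is asserted
across 20 seeds rather than at a single draw.

The `k_scan()` diagnostic reports connected components and circuit rank
(`|E| - |V| + c`) per `k` as cheap proxies for 0- and 1-dimensional
topological features. A full persistent-homology treatment of `k`
selection is intentionally not implemented; circuit rank counts all
independent cycles, including incidental triangles, so it is a guide, not
a persistence diagram.

## Problem sizes

The shipped experiments use the study conditions they model: 1000-point
sinusoid and torus datascapes at `k = 10`, 100-point circles scanned over
all `k` with 20 seeds, 200-point annuli at `k = 6`, and 2000-point
cohorts with 4-fold evaluation at `k = 10`. On one CPU the full test suite
runs in a few minutes; the heaviest single step, the 20-seed circle scan,
is about two minutes.

## Serialization

A datascape is saved as a plain-text directory: a JSON manifest (schema
tag, parameters, ids, labels, extreme ids, md5 checksums) plus TSV parts
for points, edges and hull vertex lists, all at full double precision. A
directory of diffable text parts was preferred over a zip container so
that no archiver needs to be present and version control can track
changes part by part. Loading rebuilds the datascape from the stored
coordinates and *verifies* the rebuilt edge list and extreme set against
the stored parts, so corruption or version drift is detected rather than
silently accepted. Custom metric functions cannot be serialized — only
built-in metric names round-trip.

## Known limitations

- Exact nearest-neighbor search via the full distance matrix: memory is
  $O(n^2)$, which is fine at desk scale (thousands of points) and wrong at
  millions; approximate indices are out of scope.
- Membership cost grows with the number of hulls; bounding-sphere
  prefiltering and distance-ordered short-circuiting make typical queries
  cheap, but adversarial far-inside queries still touch many hulls.
- The extreme-point search inspects dataset points only; a shape whose
  boundary passes between sample points is represented only as well as
  the sample allows.
- Volume-uniform in-shape sampling and explicit cavity geometry
  (convex-deficiency regions) are not computed.
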