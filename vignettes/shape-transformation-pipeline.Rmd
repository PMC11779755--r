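---
title: "Inferring shape transformations: stimulus generation, simulation and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring shape transformations: stimulus generation, simulation and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapescission)
```

## The problem

Can an observer who sees a shape before and after an unfamiliar geometric
transformation *apply* that transformation to a different shape? Drawing
experiments probe this by showing a **sample** and a **transformed sample**,
asking the participant to draw how a **test** shape would look under the same
transformation, and comparing the drawing against the never-shown
**transformed test** (the ground truth obtained by applying the same
deformation to the test). `shapescission` implements that entire pipeline —
stimulus construction, a synthetic-participant drawing model, and the
difference-of-distances analysis — so the full design can be generated,
simulated and analysed reproducibly.

## Shape representation and normalization

Every shape is a closed contour: an ordered list of (x, y) vertices, stored in
y-up coordinates and traversed in the canonical direction (clockwise on a
y-down canvas, i.e. positive shoelace area in stored coordinates — the same
direction the drawing task enforces). Normalization shifts each axis by its
minimum, divides **both** axes by the single resulting maximum (a shared
divisor; per-axis scaling would distort shapes and confound every similarity
measurement downstream), and then translates the polygon **area centroid** to
the origin. The area centroid is used rather than the vertex mean because it
is insensitive to how densely different parts of the contour are sampled; a
vertex-mean mode exists (`contour_centroid(..., mode = "vertex")`) for
comparison. After centering, coordinates span approximately
\([-0.5, 0.5]\): exactly so only when the centroid coincides with the
bounding-box center, which is the one place where "unit box" and "centroid at
origin" cannot both hold exactly. We follow the centroid convention because
the distance computation matches shapes by their centers.

Uniform resampling places `n` points at equal arc-length steps along the
closed polyline, starting at the first vertex. The default resolution is
`n = 100` points, enough to resolve every deformation used here while keeping
descriptor extraction at well under a millisecond per shape. One property of
polyline resampling matters for correctness and is easy to miss: resampling
is *not* idempotent on a shape whose vertices are unevenly spaced, because the
resampled polygon has slightly different chords and therefore a slightly
different arc-length parameterization. The descriptor pipeline therefore
preprocesses every shape as **normalize → resample → normalize**, which maps
an already-preprocessed shape to itself. This is what guarantees that a
drawing which reproduces the transformed test *exactly* receives exactly the
transformed test's descriptors (and a `diff` of exactly
\(-\,\mathrm{dissim}(\text{test}, \text{transformed test})\)).

## The five deformations

Each transformation is a one-parameter vector field acting on normalized
coordinates, with \(R = \sqrt{2}/2\) (half-diagonal of the unit box),
\(r = |p|\), and magnitude \(m\):

| kind | map | units |
|---|---|---|
| rotation | rotate about origin by \(m\) | radians |
| shear | \((x + m y,\; y)\) | dimensionless |
| twist | rotate by \(m\,(1 - r/R)\), clamped to 0 for \(r > R\) | radians |
| bloat | \(r \mapsto R\,(r/R)^{1/(1+m)}\), angle preserved | dimensionless |
| fisheye | \(r \mapsto R\,\tanh(m r/R)/\tanh(m)\), angle preserved | dimensionless |

All are the identity at \(m = 0\) (implemented as an exact early return).
This kind of deformation is usually illustrated only as arrow diagrams, so
these analytic forms are this package's own choice: they are the standard image-warping
definitions with the stated boundary behavior, and each is one-parameter so
that calibration is a one-dimensional search. The twist profile *decays*
with radius (a twirl) rather than growing, which keeps the outer boundary
anchored and makes the Procrustes correction meaningful: after twisting, the
result is rigidly rotated back onto the untransformed shape (rotation-only
orthogonal Procrustes, closed form) so the rigid component of the twirl is
discounted. After every kind except rotation the result is re-normalized to
the unit box; rotation is left unscaled so that its effect stays purely
rigid. Positive rotation is counterclockwise in stored y-up coordinates,
hence clockwise as seen on the y-down canvas.

## The similarity space

Drawing studies in this paradigm measure distances in ShapeComp, a trained
embedding whose Euclidean distances predict human shape-similarity
judgments. That model cannot be reproduced here, so the package uses a
transparent stand-in:
37 classical contour descriptors (log area, log perimeter, compactness,
convexity, solidity, eccentricity, principal-axis orientation as
\((\sin 2\varphi, \cos 2\varphi)\), centroid-distance Fourier harmonics
k = 1..8 with phases, curvature mean and spread, an orientation flag, and
position-Fourier harmonics of \(x + iy\) at frequencies +1, +2, +3, −1, −2),
z-scored on a reference ensemble, projected onto the top 22 principal
components (ShapeComp's published dimensionality), and rescaled so that the
root-mean-square pairwise distance over the reference ensemble is exactly
2.0. That pinned unit is what makes the design's magnitude constants
(0.65/0.9 for simple shapes, 0.55/1.0 for complex) and similarity constants
(1.5/0.5/0.15 and 2.25/1.5/0.75) usable as distances here. **No numerical
equivalence with ShapeComp is claimed**; the constants transfer in unit
convention only.

Two properties are load-bearing and tested rather than assumed:

* translation and uniform-scale invariance (normalization removes both), and
* **rotation sensitivity** — the axis-orientation encoding and the
  position-Fourier phases move when a shape rotates. A fully
  rotation-invariant space would make the rotation condition undetectable,
  collapsing one of the five factor levels of the design. Fitting with
  `orientation_sensitive = FALSE` deliberately produces a space in which
  calibrating a rotation fails, which is exercised in the tests.

Zero-variance descriptors (the orientation flag, constant after
canonicalization) are dropped with a message at fit time. The 2D map for
visual inspection (`project_2d`) is a compact exact t-SNE on the embedded
coordinates, deterministic given its seed, used for figures only.

## Magnitude calibration

`calibrate_magnitude` solves
\(\mathrm{dissim}(c, T_m c) = \text{target}\) for \(m\) over the bracket
\((0, 4]\) with tolerance 0.01 units — well below the smallest gap between
design levels (0.25 units). The distance profile is scanned on a coarse grid
for its first crossing of the target, then bisected; bisection runs until the
parameter interval is below the resolution of a 512-point grid, so both
search routes agree to one grid step on monotone profiles. Profiles in a
descriptor space are occasionally non-monotone in small ways (shear produces
±0.1-unit wiggles away from the crossing); when bisection cannot reach the
tolerance, a dense 512-point grid search plus local refinement takes over.
An unreachable target raises a calibration error naming the best achievable
distance.

## Stimulus construction

Simple-shape pools are 10-vertex random polygons (sorted polar angles, random
radii — star-shaped, hence simple by construction, and still verified by a
brute-force segment-intersection test). Complex-shape pools are smooth
radial-frequency contours (3–12 sinusoidal radius components, amplitudes
decaying with frequency), substituting for GAN-generated naturalistic
shapes, which are out of scope here. Eight sample shapes are picked per experiment: by k-means (10
restarts) on embedded coordinates, taking each cluster's nearest-to-mean pool
shape (simple), or by greedy nearest-neighbor assignment of pool shapes to
the 8 vertices of an axis-aligned cube of half-width one standard deviation
in the first three embedding dimensions (complex).

The design crosses 8 samples × 5 types × 2 magnitudes × 3 similarities = 240
conditions. Sampling 60 stimuli "with each transformation, magnitude and
similarity at least twice" is ambiguous between factor *margins* and factor
*cells*; both are implemented, with cells as the default because
30 cells × 2 = 60 exactly matches the stimulus budget — under that reading
the constraint forces exactly two selections per (type × magnitude ×
similarity) cell with randomized sample-shape assignment. The complex
experiment draws two different 40-stimulus sets (one per observer group of
10) in margins mode with a joint coverage check over their union. A third
`"none"` mode exists for minimal debug runs. Test shapes are selected from
the generation pool by exhaustive scan for the shape nearest the similarity
level's target distance; with small pools the achieved distance can deviate
from the target (a warning, not an error — the package's reduced default
pools are coarser than a 100,000-polygon pool would be).

Each trial stores the sample, transformed sample, test, and the ground-truth
transformed test built by applying the *same calibrated spec* to the test.
The start marker sits at vertex 1 after canonicalization.

## The synthetic participant

Human drawers are emulated by the simplest generative model consistent with
the task's framing that drawings lie between the test and the correctly
transformed test: a fidelity blend plus smooth contour noise,

\[\text{drawing} = \mathcal{N}\bigl((1-\lambda)\,\text{test} +
  \lambda\,\text{ttest} + \varepsilon\bigr),\]

where \(\lambda \in [0,1]\) is fidelity (0 = copies the test, 1 = applies the
transformation perfectly), \(\varepsilon\) is a per-coordinate stationary
Gaussian process along the closed contour with squared-exponential kernel
(lengthscale a fraction \(\ell\) of the perimeter, pointwise sd \(\sigma\) in
normalized units), synthesized spectrally so the curve stays closed, and
\(\mathcal{N}\) is normalization. Blending uses the index correspondence both
shapes share (drawn clockwise from the start marker, as the task enforces).
Default panel parameters — \(\lambda \sim U(0.4, 0.95)\), \(\sigma = 0.01\),
\(\ell = 0.1\) — were chosen once as a plausible moderate-fidelity panel
(humans clearly better than copying the test, far from perfect); they produce
a negative overall mean `diff`, the direction the simple-shape study found.
The model deliberately omits motor kinematics, stroke order and
shape-complexity-dependent noise, so passing tests show the *pipeline*
recovers what the generator puts in — they say nothing about human drawings
beyond the statistical layout (one drawing per participant × trial, closure
criterion, clockwise tracing).

## Analysis

For each drawing, `trial_diff` computes
`diff = dissim(drawing, transformed test) − dissim(drawing, test)` after
normalization (which implements the center matching); negative values mean
the transformation was inferred and reproduced. Aggregation reports, per
group, the mean with a t-based 95% CI and a two-sided one-sample t against
zero; across types and similarities a classical one-way F with
\((k-1, N-k)\) df; across magnitudes a two-sample t (Welch by default,
pooled optional) *and* per-level one-sample tests, because a magnitude contrast reported as t(329)
on 660 trials is consistent with per-level one-sample structure. Trials are pooled across participants, matching the printed df
pattern (659; 4, 655; 131; 219); no multiple-testing correction is applied (the
paradigm's standard reporting), with a Holm-corrected column emitted
alongside for transparency.
Non-closed or degenerate drawings are flagged invalid and excluded rather
than auto-closed, since the task UI itself enforced closure.

`recovery_experiment` sweeps panels across a fidelity grid and is the
package's own end-to-end sanity harness: the mean `diff` must decrease
monotonically in \(\lambda\), positive at \(\lambda = 0\) and negative at
\(\lambda = 1\).

## Problem sizes, determinism and limitations

The full-scale pool of 100,000 random polygons remains the default of
`run_config("simple")`, but the test suite and the acceptance script run the
pipeline on a 3,000-polygon pool with a 1,000-shape reference ensemble (and a
1,000-shape complex pool) — sizes chosen so a full run takes about a minute
while leaving k-means exemplar structure and calibration behavior intact.
Every random step routes through a named seed derived from one master seed;
reruns with the same configuration are numerically identical. Known
limitations: the stand-in similarity space is not perceptually validated; the
five field formulas are this package's own definitions, so stimuli built by
other implementations of the paradigm are not reproduced; test-shape targets
may be missed by coarse pools; and unequal per-type trial allocations seen
in some datasets are not modeled, as no allocation rule is documented for
them.

```{r example, eval = FALSE}
cfg <- run_config("simple", pool_size = 3000, n_reference = 1000, seed = 1)
run <- run_pipeline(cfg, "runs/simple")
run$summaries$overall
plot_condition_means(run$summaries$by_type)
```
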