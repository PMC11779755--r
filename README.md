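# shapescission

Stimulus generation, synthetic-drawing simulation and analysis for
shape-transformation drawing experiments.

## The problem

Observers can often tell apart the features that belong to an object's shape
from the features contributed by a transformation applied to it ("shape
scission"). One way to test this is a drawing task: show a *sample* shape
before and after an unfamiliar geometric transformation, show a different
*test* shape, and ask the participant to draw how the test would look under
the same transformation. Performance is judged against the never-shown
*transformed test* — the ground truth obtained by applying the same
deformation to the test.

`shapescission` implements that whole pipeline for closed 2D contours:

* **Contours** — arc-length resampling, normalization to the unit box with
  the area centroid at the origin, rotation-only Procrustes alignment, a
  strict endpoint-gap closure check, CSV/JSON/SVG I/O.
* **Deformations** — five one-parameter fields (twist, bloat, fisheye, shear,
  rotation) with magnitude calibration: the raw parameter is solved by
  bracketing + bisection so that the deformation moves a shape a target
  distance in the similarity space.
* **Similarity space** — a descriptor embedding standing in for a trained
  perceptual shape-similarity model: 37 contour descriptors, z-scored on a
  reference ensemble, PCA to 22 dimensions, rescaled so the reference
  root-mean-square pairwise distance is exactly 2.0. Distances `dissim(a, b)`
  in these units grade both transformation magnitude and sample–test
  similarity.
* **Stimuli** — random-polygon and radial-frequency shape generators, k-means
  and cube-vertex exemplar selection, the 8 x 5 x 2 x 3 factorial design
  (240 conditions) and constrained sampling (every type x magnitude x
  similarity cell at least twice).
* **Synthetic participants** — drawings simulated as
  `normalize((1 - lambda) * test + lambda * transformed_test + noise)` with
  fidelity `lambda` and smooth periodic Gaussian-process contour noise.
* **Analysis** — the per-drawing statistic
  `diff = dissim(drawing, transformed test) - dissim(drawing, test)`
  (negative = the transformation was inferred and reproduced), aggregated as
  one-sample t tests per condition, one-way F across types/similarities, and
  a magnitude contrast.

## Worked example

A reduced end-to-end run of the simple-shape experiment (3,000-polygon pool,
1,000-shape reference ensemble; about a minute on one core):

```r
library(shapescission)
cfg <- run_config("simple", pool_size = 3000, n_reference = 1000, seed = 1)
run <- run_pipeline(cfg, "runs/simple")
run$summaries$overall
#> Difference-of-distances summary (overall)
#>    group   n mean_diff     sd   ci_lo   ci_hi      t  df         p    p_holm
#>  overall 660   -0.2668 0.2948 -0.2893 -0.2442 -23.25 659 9.392e-88 9.392e-88
```

660 drawings (11 synthetic participants x 60 stimuli). The mean `diff` is
negative with the confidence interval far from zero: the simulated panel's
drawings sit closer to the transformed test than to the untransformed test,
which is exactly what the panel's fidelity parameters (lambda between 0.4 and
0.95) put in. The one-sample df of 659, the per-type df of 131 and the
one-way F df of (4, 655) reproduce the canonical df pattern of the pooled
660-trial design.

The fidelity recovery sweep shows the statistic tracking the generative
parameter:

```r
rec <- recovery_experiment(c(0, 0.5, 1), panel_size = 2,
                           run$trials[1:20], run$space, sigma = 0.01, seed = 1)
rec[, c("lambda", "n", "mean_diff", "t", "df")]
#>   lambda  n mean_diff       t df
#> 1    0.0 40     0.696  21.239 39
#> 2    0.5 40    -0.033  -1.662 39
#> 3    1.0 40    -0.682 -22.764 39
```

At `lambda = 0` (participants copy the test) the mean diff is positive; at
`lambda = 1` (perfect transformation) it equals minus the mean test
separation; in between it passes through zero.

See `vignettes/shape-transformation-pipeline.Rmd` for the model, the
parameter choices and the numerical decisions.

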