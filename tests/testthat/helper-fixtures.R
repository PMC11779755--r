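# Shared fixtures, built once per test run and memoized. All sizes are kept
# modest so the whole suite stays fast; the generators themselves are what is
# under test, so fixtures are always built by package code, never stored.

.fx <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_pool <- function() memo("pool", function() {
  generate_random_polygons(1500, vertices = 10L, seed = 2024L)
})

fx_space <- function() memo("space", function() {
  suppressMessages(fit_shape_space(fx_pool()[1:1000], d = 22L))
})

fx_exemplars <- function() memo("exemplars", function() {
  select_cluster_exemplars(fx_pool(), 8L, fx_space(), seed = 11L)
})

fx_design <- function() memo("design", function() {
  sample_design(enumerate_design(8L), 60L, "cells", seed = 7L)
})

fx_trials <- function() memo("trials", function() {
  suppressWarnings(build_trials(fx_design(), fx_exemplars(), fx_pool(),
                                fx_space()))
})

# a small regular-ish test contour: irregular but convex 10-gon
fx_decagon <- function() {
  ang <- 2 * pi * (0:9) / 10
  contour(cbind((1 + 0.2 * cos(3 * ang)) * cos(ang),
                (1 + 0.2 * cos(3 * ang)) * sin(ang)))
}

rotate_contour <- function(c, theta) {
  p <- unclass(c)[, 1:2]
  contour(cbind(cos(theta) * p[, 1] - sin(theta) * p[, 2],
                sin(theta) * p[, 1] + cos(theta) * p[, 2]))
}
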