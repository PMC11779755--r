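test_that("displacement fields satisfy their defining point mappings", {
  expect_equal(displacement_field("rotation", pi / 2, rbind(c(0.5, 0))),
               rbind(c(0, 0.5)), tolerance = 1e-12)
  p <- rbind(c(0.2, -0.3), c(-0.1, 0.4))
  for (k in transform_kinds())
    expect_equal(displacement_field(k, 0, p), p, tolerance = 1e-12,
                 label = paste("identity at zero for", k))
  expect_equal(displacement_field("shear", 0.5, rbind(c(0.1, 0.4))),
               rbind(c(0.1 + 0.5 * 0.4, 0.4)))
  # twist leaves the reference radius R fixed
  R <- sqrt(2) / 2
  pr <- rbind(c(R, 0), c(0, -R))
  expect_equal(displacement_field("twist", 1.0, pr), pr, tolerance = 1e-12)
  # bloat/fisheye are radial with the stated profiles
  r0 <- 0.3
  b <- displacement_field("bloat", 0.5, rbind(c(r0, 0)))
  expect_equal(b[1, 1], R * (r0 / R)^(1 / 1.5), tolerance = 1e-12)
  f <- displacement_field("fisheye", 2, rbind(c(0, r0)))
  expect_equal(f[1, 2], R * tanh(2 * r0 / R) / tanh(2), tolerance = 1e-12)
  expect_error(displacement_field("bloat", -0.1, p), "nonnegative")
  expect_error(displacement_field("fisheye", -1, p), "nonnegative")
  expect_error(displacement_field("wobble", 1, p))
})

test_that("apply_transform honors full-turn rotation and zero magnitudes", {
  c0 <- resample_uniform(normalize_contour(fx_decagon()), 60)
  full <- apply_transform(c0, transform_spec("rotation", 2 * pi))
  expect_lt(max(abs(unclass(full)[, 1:2] - unclass(c0)[, 1:2])), 1e-9)
  for (k in transform_kinds())
    expect_identical(apply_transform(c0, transform_spec(k, 0)), c0)
  # deterministic: identical inputs give identical outputs
  s <- transform_spec("twist", 0.8)
  expect_identical(apply_transform(c0, s), apply_transform(c0, s))
})

test_that("bloat maps a centered circle by the closed-form radial rule", {
  ang <- 2 * pi * (0:63) / 64
  circ <- contour(cbind(0.3 * cos(ang), 0.3 * sin(ang)))
  out <- apply_transform(circ, transform_spec("bloat", 0.5))
  # oracle: closed-form radius, then the same re-normalization step
  R <- sqrt(2) / 2
  r2 <- R * (0.3 / R)^(1 / 1.5)
  oracle <- normalize_contour(contour(cbind(r2 * cos(ang), r2 * sin(ang))))
  expect_lt(max(abs(unclass(out)[, 1:2] - unclass(oracle)[, 1:2])), 1e-9)
  # any centered circle re-normalizes to radius 1/2
  expect_equal(max(sqrt(rowSums(unclass(out)[, 1:2]^2))), 0.5, tolerance = 1e-9)
})

test_that("apply_transform preserves point count and correspondence", {
  c0 <- resample_uniform(normalize_contour(fx_pool()[[5]]), 80)
  for (k in transform_kinds()) {
    out <- apply_transform(c0, transform_spec(k, 0.4))
    expect_equal(nrow(out), 80L)
  }
  # twist includes the procrustes correction: twisting then correcting beats
  # twisting alone at matching the source
  tw_raw <- displacement_field("twist", 1.2, unclass(c0)[, 1:2])
  tw_raw <- normalize_contour(contour(tw_raw))
  tw <- apply_transform(c0, transform_spec("twist", 1.2))
  rss <- function(a, b) sum((unclass(a)[, 1:2] - unclass(b)[, 1:2])^2)
  expect_lte(rss(tw, c0), rss(tw_raw, c0) + 1e-9)
})

test_that("zero magnitude produces zero similarity-space displacement", {
  sp <- fx_space()
  c0 <- resample_uniform(normalize_contour(fx_pool()[[3]]), 100)
  for (k in transform_kinds())
    expect_lt(dissim(c0, apply_transform(c0, transform_spec(k, 0)), sp), 1e-6)
})

test_that("calibration hits its target and recovers planted parameters", {
  sp <- fx_space()
  c0 <- resample_uniform(normalize_contour(fx_exemplars()[[2]]), 100)
  spec <- calibrate_magnitude(c0, "bloat", 0.9, sp)
  expect_lte(abs(spec$calibrated_units - 0.9), 0.01)
  achieved <- dissim(c0, apply_transform(c0, spec), sp)
  expect_lte(abs(achieved - 0.9), 0.01)

  # plant a known parameter and recover it through its own distance
  # (bloat has a smooth strictly increasing distance profile, so the
  # parameter is identifiable)
  m0 <- 0.8
  target <- dissim(c0, apply_transform(c0, transform_spec("bloat", m0)), sp)
  rec <- calibrate_magnitude(c0, "bloat", target, sp)
  expect_lte(abs(rec$calibrated_units - target), 0.01)
  expect_lt(abs(rec$raw_param - m0), 0.05)
})

test_that("calibration fails informatively on rotation-blind symmetric input", {
  pool <- fx_pool()
  sp_blind <- suppressWarnings(suppressMessages(
    fit_shape_space(pool[1:300], d = 12L, orientation_sensitive = FALSE)))
  ang <- 2 * pi * (0:99) / 100
  circ <- contour(cbind(0.5 * cos(ang), 0.5 * sin(ang)))
  err <- tryCatch(calibrate_magnitude(circ, "rotation", 0.65, sp_blind),
                  error = function(e) e)
  expect_s3_class(err, "shapescission_calibration_failure")
  expect_lt(err$best_achievable, 0.1)
})

test_that("similarity distance is nondecreasing in magnitude near the design range", {
  sp <- fx_space()
  ms <- c(0.1, 0.5, 1, 1.5, 2)
  for (i in c(1, 4)) {
    c0 <- resample_uniform(normalize_contour(fx_exemplars()[[i]]), 100)
    base <- embed_contour(sp, c0)
    for (k in transform_kinds()) {
      d <- vapply(ms, function(m) {
        sqrt(sum((embed_contour(sp, apply_transform(c0, transform_spec(k, m))) -
                    base)^2))
      }, numeric(1))
      expect_true(all(diff(d) > -0.15),
                  label = sprintf("near-monotone distance for %s on exemplar %d", k, i))
    }
  }
})
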