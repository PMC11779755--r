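test_that("random polygons are simple, 10-vertex, and seed-reproducible", {
  polys <- generate_random_polygons(5, vertices = 10L, seed = 4L)
  expect_length(polys, 5L)
  expect_true(all(vapply(polys, nrow, integer(1)) == 10L))
  expect_true(all(vapply(polys, is_simple_polygon, logical(1))))

  again <- generate_random_polygons(5, vertices = 10L, seed = 4L)
  expect_identical(lapply(polys, unclass), lapply(again, unclass))

  big <- generate_random_polygons(1000, seed = 12L)
  expect_true(all(vapply(big, is_simple_polygon, logical(1))))
  # normalized on output
  expect_true(all(vapply(big[1:50], function(p)
    max(abs(contour_centroid(p))) < 1e-9, logical(1))))
})

test_that("complex shapes are simple smooth contours with cube exemplars", {
  shapes <- generate_complex_shapes(40, seed = 3L)
  expect_length(shapes, 40L)
  expect_true(all(vapply(shapes, is_simple_polygon, logical(1))))

  sp <- fx_space()
  sel <- generate_complex_shapes(300, seed = 3L, space = sp)
  expect_length(sel$shapes, 300L)
  expect_length(sel$exemplar_idx, 8L)
  expect_equal(length(unique(sel$exemplar_idx)), 8L)

  # greedy assignment beats 10,000 random assignments of 8 distinct shapes
  emb <- t(vapply(sel$shapes, function(s) embed_contour(sp, s), numeric(sp$d)))
  e3 <- emb[, 1:3]
  sds <- apply(e3, 2, sd); ctr <- colMeans(e3)
  cube <- sweep(sweep(as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
                      2, sds, "*"), 2, ctr, "+")
  D <- sqrt(pmax(0, outer(rowSums(cube^2), rowSums(e3^2), "+") -
                   2 * tcrossprod(cube, e3)))
  set.seed(8)
  rand_costs <- replicate(10000, sum(D[cbind(1:8, sample(300, 8))]))
  expect_lte(sel$assignment_cost, min(rand_costs))

  expect_error(generate_complex_shapes(5, seed = 1L, space = sp), "at least 8")
})

test_that("k-means exemplars are the nearest-to-centroid pool members", {
  sp <- fx_space()
  # 8 well-separated tight blobs: distinct base shapes, tiny perturbations
  bases <- fx_exemplars()
  blob <- list(); blob_id <- integer(0)
  set.seed(21)
  for (b in seq_along(bases)) {
    p0 <- unclass(resample_uniform(normalize_contour(bases[[b]]), 60))[, 1:2]
    for (r in 1:6) {
      blob <- c(blob, list(contour(p0 + matrix(rnorm(120, sd = 0.002), ncol = 2))))
      blob_id <- c(blob_id, b)
    }
  }
  ex <- select_cluster_exemplars(blob, 8L, sp, seed = 5L)
  picked <- blob_id[attr(ex, "pool_index")]
  expect_setequal(picked, 1:8)

  # brute-force check: each exemplar is the pool point nearest its center
  pool <- fx_pool()[1:200]
  ex3 <- select_cluster_exemplars(pool, 3L, sp, seed = 9L)
  emb <- t(vapply(pool, function(s) embed_contour(sp, s), numeric(sp$d)))
  centers <- attr(ex3, "centers")
  for (j in 1:3) {
    d2 <- colSums((t(emb) - centers[j, ])^2)
    expect_equal(attr(ex3, "pool_index")[j], which.min(d2))
  }

  # k = pool size: every shape its own cluster
  small <- fx_pool()[31:36]
  exall <- select_cluster_exemplars(small, 6L, sp, seed = 2L)
  expect_setequal(attr(exall, "pool_index"), 1:6)
  expect_error(select_cluster_exemplars(small, 7L, sp), "exceeds")
})

test_that("test-shape selection matches an exhaustive scan", {
  sp <- fx_space()
  pool <- fx_pool()[1:500]
  sample_shape <- fx_exemplars()[[1]]
  tgt <- 0.8
  sel <- suppressWarnings(select_test_shape(sample_shape, pool, tgt, sp))
  es <- embed_contour(sp, sample_shape)
  d <- vapply(pool, function(s) sqrt(sum((embed_contour(sp, s) - es)^2)),
              numeric(1))
  cand <- which(d > 1e-12)
  expect_equal(attr(sel, "pool_index"),
               cand[which.min(abs(d[cand] - tgt))])
  expect_equal(attr(sel, "achieved_units"), min_by <- d[attr(sel, "pool_index")])

  # a shape at exactly the target distance wins; the sample itself is excluded
  exact_pool <- c(pool[1:20], list(sel))
  sel2 <- suppressWarnings(select_test_shape(sample_shape, exact_pool,
                                             attr(sel, "achieved_units"), sp))
  expect_equal(attr(sel2, "pool_index"), 21L)
  withsample <- c(list(sample_shape), pool[1:20])
  near <- suppressWarnings(select_test_shape(sample_shape, withsample, 0.001, sp))
  expect_gt(attr(near, "pool_index"), 1L)
})
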