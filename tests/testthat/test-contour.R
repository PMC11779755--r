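test_that("uniform resampling spaces points equally by arc length", {
  sq <- contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  r8 <- resample_uniform(sq, 8)
  expect_equal(nrow(r8), 8L)
  # corners and edge midpoints, starting at the first vertex
  expected <- rbind(c(0, 0), c(0.5, 0), c(1, 0), c(1, 0.5),
                    c(1, 1), c(0.5, 1), c(0, 1), c(0, 0.5))
  expect_equal(unclass(r8)[, 1:2], expected, ignore_attr = TRUE)

  # samples at multiples of perimeter/100 land on the square's edges exactly
  r100 <- resample_uniform(sq, 100)
  seg <- sqrt(rowSums((unclass(r100)[c(2:100, 1), 1:2] -
                         unclass(r100)[, 1:2])^2))
  expect_lt(max(abs(seg - 4 / 100)), 1e-9)
  expect_lt(abs(contour_perimeter(r100) - 4) / 4, 1e-6)

  # irregular 10-gon: arc positions along the source polyline are exact
  # multiples of perimeter/100 (oracle: brute-force point-on-polyline search)
  dec <- fx_decagon()
  rd <- resample_uniform(dec, 100)
  p <- unclass(dec)[, 1:2]
  nverts <- nrow(p)
  segs <- p[c(2:nverts, 1), ] - p
  slen <- sqrt(rowSums(segs^2))
  cum <- c(0, cumsum(slen))
  arc_pos <- function(q) {
    for (j in seq_len(nverts)) {
      v <- q - p[j, ]
      t <- sum(v * segs[j, ]) / slen[j]^2
      if (t >= -1e-12 && t <= 1 + 1e-12 &&
          sqrt(sum((p[j, ] + t * segs[j, ] - q)^2)) < 1e-9)
        return(cum[j] + t * slen[j])
    }
    NA_real_
  }
  pos <- apply(unclass(rd)[, 1:2], 1, arc_pos)
  expect_true(all(is.finite(pos)))
  L <- contour_perimeter(dec)
  expect_lt(max(abs(pos - L * (0:99) / 100)), 1e-9)
})

test_that("resampling an already uniform contour is the identity", {
  ang <- 2 * pi * (0:63) / 64
  circ <- contour(cbind(cos(ang), sin(ang)))   # equal chords by construction
  r2 <- resample_uniform(circ, 64)
  expect_lt(max(abs(unclass(r2)[, 1:2] - unclass(circ)[, 1:2])), 1e-9)
  sq8 <- resample_uniform(contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 8)
  expect_lt(max(abs(unclass(resample_uniform(sq8, 8))[, 1:2] -
                      unclass(sq8)[, 1:2])), 1e-12)
})

test_that("resampling rejects degenerate input and preserves convex area", {
  collapsed <- structure(matrix(1, nrow = 4, ncol = 2,
                                dimnames = list(NULL, c("x", "y"))),
                         class = c("contour", "matrix"))
  expect_error(resample_uniform(collapsed, 10), "degenerate|zero")
  ang <- 2 * pi * (0:11) / 12
  conv <- contour(cbind(cos(ang) * 1.3, sin(ang)))
  r <- resample_uniform(conv, 100)
  expect_lt(abs(contour_area(r) - contour_area(conv)) / contour_area(conv),
            0.01)
})

test_that("normalization centers the centroid and preserves aspect ratio", {
  sq <- contour(rbind(c(2, 2), c(4, 2), c(4, 4), c(2, 4)))
  n <- normalize_contour(sq)
  expect_equal(sort(unique(round(unclass(n)[, 1], 12))), c(-0.5, 0.5))
  expect_lt(max(abs(contour_centroid(n))), 1e-9)

  # 3-4-5 right triangle: area centroid at the vertex mean, extent 1, aspect 3/4
  tri <- contour(rbind(c(0, 0), c(4, 0), c(4, 3)))
  nt <- normalize_contour(tri)
  p <- unclass(nt)[, 1:2]
  expect_equal(max(apply(p, 2, function(v) diff(range(v)))), 1)
  expect_equal(diff(range(p[, 2])) / diff(range(p[, 1])), 3 / 4)
  expect_lt(max(abs(contour_centroid(nt))), 1e-9)
  # analytic area centroid of the triangle is the vertex mean (8/3, 1);
  # the normalized first vertex must therefore sit at -centroid/scale
  expect_equal(p[1, ], c(-8 / 3, -1) / 4, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("normalization is idempotent and commutes with rotation", {
  dec <- fx_decagon()
  n1 <- normalize_contour(dec)
  n2 <- normalize_contour(n1)
  expect_lt(max(abs(unclass(n1)[, 1:2] - unclass(n2)[, 1:2])), 1e-9)

  th <- 0.7
  a <- normalize_contour(rotate_contour(normalize_contour(dec), th))
  b <- normalize_contour(rotate_contour(dec, th))
  expect_lt(max(abs(unclass(a)[, 1:2] - unclass(b)[, 1:2])), 1e-9)

  collapsed <- structure(matrix(2, nrow = 3, ncol = 2,
                                dimnames = list(NULL, c("x", "y"))),
                         class = c("contour", "matrix"))
  expect_error(normalize_contour(collapsed), "degenerate|zero")
})

test_that("constructor canonicalizes orientation and drops duplicates", {
  ccw <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))   # positive shoelace
  cw <- ccw[c(1, 4, 3, 2), ]                          # negative shoelace
  a <- contour(ccw); b <- contour(cw)
  expect_equal(unclass(a)[, 1:2], unclass(b)[, 1:2], ignore_attr = TRUE)
  withdup <- rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 1), c(1, 1), c(0, 1), c(0, 0))
  expect_equal(nrow(contour(withdup)), 4L)
  expect_error(contour(rbind(c(0, 0), c(1, 1))), "at least 3")
})

test_that("procrustes rotation recovers planted rotations exactly", {
  ref <- resample_uniform(normalize_contour(fx_decagon()), 50)
  rot <- rotate_contour(ref, 0.3)
  back <- procrustes_rotate(rot, ref)
  expect_lt(max(abs(unclass(back)[, 1:2] - unclass(ref)[, 1:2])), 1e-9)
  same <- procrustes_rotate(ref, ref)
  expect_lt(abs(attr(same, "procrustes_angle")), 1e-12)
  expect_error(procrustes_rotate(resample_uniform(ref, 40), ref),
               "mismatch")
})

test_that("procrustes residual never exceeds a dense grid-search oracle", {
  set.seed(101)
  thetas <- 2 * pi * (0:3599) / 3600
  for (case in 1:100) {
    p <- matrix(rnorm(100), ncol = 2)
    q <- matrix(rnorm(100), ncol = 2)
    a <- contour(p); b <- contour(q)
    pr <- procrustes_rotate(a, b)
    res_pr <- sum((unclass(pr)[, 1:2] - unclass(b)[, 1:2])^2)
    # grid oracle via the complex cross-correlation identity
    pa <- unclass(a)[, 1:2]; pb <- unclass(b)[, 1:2]
    z <- complex(real = pa[, 1], imaginary = pa[, 2])
    w <- complex(real = pb[, 1], imaginary = pb[, 2])
    s <- sum(z * Conj(w))
    res_grid <- sum(Mod(z)^2) + sum(Mod(w)^2) -
      2 * max(Re(exp(1i * thetas) * s))
    expect_lte(res_pr, res_grid + 1e-9)
  }
})

test_that("closure check uses a strict endpoint-gap inequality", {
  expect_true(is_closed(rbind(c(0, 0), c(5, 5), c(0, 0))))
  expect_false(is_closed(rbind(c(0, 0), c(25, 0), c(50, 0)), gap_threshold = 10))
  expect_true(is_closed(rbind(c(0, 0), c(5, 0), c(9.99, 0)), gap_threshold = 10))
  expect_false(is_closed(rbind(c(0, 0), c(5, 0), c(10, 0)), gap_threshold = 10))
})

test_that("self-intersection test flags crossing polylines", {
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_false(is_simple_polygon(structure(bow, class = c("contour", "matrix"))))
  expect_true(is_simple_polygon(contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))))
})
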