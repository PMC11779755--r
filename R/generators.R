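#' Random simple polygons
#'
#' Generates simple (non-self-intersecting) closed polygons by sampling
#' `vertices` sorted polar angles and radii about the origin; star-shaped
#' polygons built this way cannot self-intersect, but every candidate is
#' checked with [is_simple_polygon()] and resampled if it fails (e.g. through
#' coincident angles). Each polygon is normalized. Deterministic given
#' `seed`.
#'
#' @param count number of polygons.
#' @param vertices vertex count per polygon (default 10).
#' @param seed integer seed.
#' @param r_range radius range the vertices are drawn from.
#' @return list of `count` normalized [contour()]s.
#' @export
generate_random_polygons <- function(count, vertices = 10L, seed = 1L,
                                     r_range = c(0.15, 1)) {
  stopifnot(count >= 1, vertices >= 3)
  with_seed(seed, {
    lapply(seq_len(count), function(i) {
      repeat {
        ang <- sort(stats::runif(vertices, 0, 2 * pi))
        rad <- stats::runif(vertices, r_range[1], r_range[2])
        if (min(diff(ang)) < 1e-6) next
        cand <- contour(cbind(rad * cos(ang), rad * sin(ang)),
                        meta = sprintf("poly_%d", i))
        if (is_simple_polygon(cand)) return(normalize_contour(cand))
      }
    })
  })
}

#' Smooth radial-frequency shapes
#'
#' Generates smooth, naturalistic-looking closed contours as radial-frequency
#' patterns: the radius as a function of polar angle is modulated by 3 to 12
#' sinusoidal components with random phases and amplitudes decaying with
#' frequency. Being star-shaped, the contours are simple by construction.
#' Optionally, an exemplar-selection pass picks the 8 shapes whose first
#' three embedding coordinates best match the vertices of an axis-aligned
#' cube of half-width one reference standard deviation (per dimension), by
#' greedy nearest-neighbor assignment — the device used to spread complex
#' sample shapes widely through shape space.
#'
#' @param count number of shapes to generate (>= 8 when exemplars are
#'   requested).
#' @param seed integer seed.
#' @param n_points boundary samples per shape.
#' @param space optional fitted [fit_shape_space()]; when supplied, cube
#'   exemplars are selected and returned.
#' @param feasible optional predicate applied to candidate exemplars (see
#'   [select_cluster_exemplars()]); shapes failing it are excluded from the
#'   cube assignment and the assignment repeated.
#' @return when `space` is `NULL`, a list of contours; otherwise a list with
#'   elements `shapes` (the full pool), `exemplar_idx` (indices of the 8 cube
#'   exemplars) and `assignment_cost` (total embedding distance of the
#'   greedy assignment).
#' @export
generate_complex_shapes <- function(count, seed = 1L, n_points = 120L,
                                    space = NULL, feasible = NULL) {
  stopifnot(count >= 1)
  if (!is.null(space) && count < 8)
    stop("need at least 8 shapes to fill the 8 cube vertices")
  shapes <- with_seed(seed, {
    lapply(seq_len(count), function(i) {
      repeat {
        k <- sort(sample(2:14, sample(3:12, 1)))
        amp <- stats::runif(length(k), 0.2, 1) / k^1.1
        phase <- stats::runif(length(k), 0, 2 * pi)
        th <- 2 * pi * (0:(n_points - 1)) / n_points
        r <- 1 + colSums(amp * sin(outer(k, th) + phase))
        if (min(r) <= 0.05) next
        cand <- contour(cbind(r * cos(th), r * sin(th)),
                        meta = sprintf("complex_%d", i))
        if (is_simple_polygon(cand)) return(normalize_contour(cand))
      }
    })
  })
  if (is.null(space)) return(shapes)
  emb <- t(vapply(shapes, function(s) embed_contour(space, s),
                  numeric(space$d)))
  e3 <- emb[, 1:3, drop = FALSE]
  sds <- apply(e3, 2, stats::sd)
  ctr <- colMeans(e3)
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  cube <- sweep(sweep(cube, 2, sds, "*"), 2, ctr, "+")
  active <- seq_len(nrow(e3))
  repeat {
    if (length(active) < 8) stop("too few feasible shapes for the 8 cube vertices")
    sel <- greedy_assign(cube, e3[active, , drop = FALSE])
    idx <- active[sel$idx]
    if (is.null(feasible)) break
    ok <- vapply(idx, function(i) isTRUE(feasible(shapes[[i]])), logical(1))
    if (all(ok)) break
    active <- setdiff(active, idx[!ok])
  }
  list(shapes = shapes, exemplar_idx = idx, assignment_cost = sel$cost)
}

# Greedy nearest-neighbor assignment of targets (rows of `targets`) to
# distinct rows of `points`: repeatedly commit the globally closest
# unassigned (target, point) pair.
greedy_assign <- function(targets, points) {
  nt <- nrow(targets)
  D <- outer(rowSums(targets^2), rowSums(points^2), "+") -
    2 * tcrossprod(targets, points)
  D[D < 0] <- 0
  D <- sqrt(D)
  idx <- integer(nt)
  cost <- 0
  for (step in seq_len(nt)) {
    j <- which(D == min(D), arr.ind = TRUE)[1, ]
    idx[j[1]] <- j[2]
    cost <- cost + D[j[1], j[2]]
    D[j[1], ] <- Inf
    D[, j[2]] <- Inf
  }
  list(idx = idx, cost = cost)
}

#' Cluster exemplars in shape space
#'
#' Runs k-means (10 restarts, best within-cluster sum of squares) on the
#' embedded coordinates of a shape pool and returns, for each cluster, the
#' pool shape nearest to the cluster mean — the procedure used to pick the 8
#' sample shapes from the random-polygon pool. Deterministic given `seed`.
#'
#' @param pool list of [contour()]s.
#' @param k number of clusters.
#' @param space a fitted [fit_shape_space()].
#' @param seed integer seed for the k-means starts.
#' @param feasible optional predicate `function(contour) TRUE/FALSE`; each
#'   cluster then contributes its nearest-to-mean member that passes the
#'   predicate (used to screen sample shapes for calibration feasibility).
#' @return list of `k` contours; attribute `"pool_index"` gives their indices
#'   into `pool`.
#' @export
select_cluster_exemplars <- function(pool, k, space, seed = 1L,
                                     feasible = NULL) {
  if (k > length(pool)) stop("k exceeds pool size")
  emb <- t(vapply(pool, function(s) embed_contour(space, s), numeric(space$d)))
  if (k == length(pool)) {   # every shape is its own cluster
    out <- pool
    attr(out, "pool_index") <- seq_len(k)
    attr(out, "centers") <- emb
    return(out)
  }
  km <- with_seed(seed,
                  stats::kmeans(emb, centers = k, nstart = 10, iter.max = 100))
  idx <- vapply(seq_len(k), function(j) {
    d2 <- colSums((t(emb) - km$centers[j, ])^2)
    if (is.null(feasible)) return(which.min(d2))
    members <- which(km$cluster == j)
    for (i in members[order(d2[members])])
      if (isTRUE(feasible(pool[[i]]))) return(i)
    stop(sprintf("no feasible exemplar in cluster %d", j))
  }, integer(1))
  out <- pool[idx]
  attr(out, "pool_index") <- idx
  attr(out, "centers") <- km$centers
  out
}

#' Check whether similarity targets are reachable on a shape
#'
#' A magnitude target is reachable for a deformation kind when the distance
#' profile `dissim(c, T_m c)` attains the target somewhere over the bracket
#' (the profile is continuous and starts at 0, so reaching the target on a
#' coarse grid guarantees a crossing). Used to screen candidate sample shapes
#' before calibration — deformations with bounded profiles (bloat saturates
#' as the shape approaches a disc) cannot reach every target on every shape.
#'
#' @param c a [contour()].
#' @param target the largest magnitude target that must be reachable (units).
#' @param space a fitted [fit_shape_space()].
#' @param kinds deformation kinds to require.
#' @param bracket raw-parameter range, as in [calibrate_magnitude()].
#' @param grid_n probe points per kind.
#' @return `TRUE` if every kind can reach `target`.
#' @export
can_reach_targets <- function(c, target, space, kinds = transform_kinds(),
                              bracket = c(0, 4), grid_n = 16L) {
  p <- resample_uniform(normalize_contour(as_contour(c)), space$n_points)
  base <- embed_contour(space, p)
  grid <- seq(bracket[1], bracket[2], length.out = grid_n + 1L)[-1]
  for (k in kinds) {
    reached <- FALSE
    for (m in rev(grid)) {   # large magnitudes usually decide fastest
      d <- sqrt(sum((embed_contour(
        space, apply_transform(p, transform_spec(k, m))) - base)^2))
      if (d >= target) { reached <- TRUE; break }
    }
    if (!reached) return(FALSE)
  }
  TRUE
}

#' Pick the pool shape nearest a target dissimilarity from a sample
#'
#' Exhaustively scans the pool for the shape whose distance to `sample`
#' is closest to `target_units`, excluding the sample itself; ties are broken
#' by the lowest pool index. Emits a warning when the achieved distance
#' deviates from the target by more than `warn_tol` units (coarse pools may
#' not contain a close match).
#'
#' @param sample a [contour()].
#' @param pool list of candidate [contour()]s.
#' @param target_units desired distance in similarity units (> 0).
#' @param space a fitted [fit_shape_space()].
#' @param warn_tol deviation that triggers a warning (units).
#' @return the selected contour, with attributes `"achieved_units"` and
#'   `"pool_index"`.
#' @export
select_test_shape <- function(sample, pool, target_units, space,
                              warn_tol = 0.05) {
  stopifnot(length(pool) >= 1, target_units > 0)
  es <- embed_contour(space, sample)
  d <- vapply(pool, function(s) sqrt(sum((embed_contour(space, s) - es)^2)),
              numeric(1))
  cand <- which(d > 1e-12)               # exclude the sample itself
  if (!length(cand)) stop("pool contains no shape distinct from the sample")
  j <- cand[which.min(abs(d[cand] - target_units))]
  if (abs(d[j] - target_units) > warn_tol)
    warning(sprintf("test-shape distance %.3f deviates from target %.3f by > %.2f units",
                    d[j], target_units, warn_tol))
  out <- pool[[j]]
  attr(out, "achieved_units") <- d[j]
  attr(out, "pool_index") <- j
  out
}
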