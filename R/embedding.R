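#' Shape descriptor vector
#'
#' Computes the fixed 37-dimensional descriptor roster for a contour, after
#' normalization and uniform resampling to `n_points`. The roster (version
#' `"v1"`) comprises: log area, log perimeter, compactness \eqn{4\pi A/P^2},
#' convexity (hull perimeter / perimeter), solidity (area / hull area),
#' eccentricity, the principal-axis orientation encoded as
#' \eqn{(\sin 2\varphi, \cos 2\varphi)}, centroid-distance Fourier harmonics
#' k = 1..8 as real/imaginary pairs (phases retained relative to the start
#' vertex), mean and standard deviation of discrete curvature, a signed-area
#' orientation flag, and position Fourier harmonics of the complex boundary
#' signal x + iy at frequencies +1, +2, +3, -1, -2 as real/imaginary pairs.
#'
#' The position-Fourier and axis-orientation entries make the descriptor
#' rotation-*sensitive*; all entries are invariant to translation and uniform
#' scaling because the contour is normalized first.
#'
#' @param c a [contour()].
#' @param n_points resampling resolution (default 100).
#' @return named numeric vector of length 37.
#' @export
shape_descriptors <- function(c, n_points = 100L) {
  # normalize -> resample -> normalize: the second normalization makes the
  # preprocessing idempotent (a shape that is already uniformly resampled and
  # normalized maps to itself), so a drawing that reproduces a stimulus
  # exactly gets exactly the stimulus descriptors
  p <- normalize_contour(resample_uniform(normalize_contour(as_contour(c)),
                                          n_points))
  n <- nrow(p)
  A <- contour_area(p)
  P <- contour_perimeter(p)
  if (A <= 0 || P <= 0) stop_degenerate("degenerate contour: zero area or perimeter")

  hull_idx <- grDevices::chull(p[, 1], p[, 2])
  hull <- contour(p[hull_idx, , drop = FALSE])
  A_hull <- contour_area(hull)
  P_hull <- contour_perimeter(hull)

  cv <- stats::cov(p)
  eg <- eigen(cv, symmetric = TRUE)
  ecc <- sqrt(max(0, 1 - eg$values[2] / max(eg$values[1], 1e-15)))
  phi <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])

  r <- sqrt(rowSums(p^2))                 # centroid at origin after normalize
  fr <- stats::fft(r) / n
  kd <- 1:8
  cdist <- as.vector(rbind(Re(fr[kd + 1]), Im(fr[kd + 1])))

  edges <- p[c(2:n, 1L), , drop = FALSE] - p
  elen <- sqrt(rowSums(edges^2))
  head_ang <- atan2(edges[, 2], edges[, 1])
  turn <- diff(c(head_ang, head_ang[1]))
  turn <- (turn + pi) %% (2 * pi) - pi
  ds <- (elen + elen[c(2:n, 1L)]) / 2
  kappa <- turn / pmax(ds, 1e-12)

  z <- stats::fft(complex(real = p[, 1], imaginary = p[, 2])) / n
  pk <- c(2L, 3L, 4L, n, n - 1L)          # frequencies +1, +2, +3, -1, -2
  posf <- as.vector(rbind(Re(z[pk]), Im(z[pk])))

  out <- c(
    log_area = log(A),
    log_perimeter = log(P),
    compactness = 4 * pi * A / P^2,
    convexity = P_hull / P,
    solidity = A / A_hull,
    eccentricity = ecc,
    axis_sin2 = sin(2 * phi),
    axis_cos2 = cos(2 * phi),
    stats::setNames(cdist, paste0("cdist_", rep(kd, each = 2), c("_re", "_im"))),
    curvature_mean = mean(kappa),
    curvature_sd = stats::sd(kappa),
    orientation_flag = sign(shoelace_area(p)),
    stats::setNames(posf, paste0("posf_", rep(c("p1", "p2", "p3", "m1", "m2"),
                                              each = 2), c("_re", "_im")))
  )
  if (anyNA(out) || any(!is.finite(out)))
    stop_degenerate("non-finite descriptor values")
  out
}

descriptor_roster_version <- "v1"

orientation_descriptor_names <- function() {
  c("axis_sin2", "axis_cos2",
    paste0("posf_", rep(c("p1", "p2", "p3", "m1", "m2"), each = 2),
           c("_re", "_im")))
}

#' Fit a perceptual shape-similarity embedding space
#'
#' Builds the embedding used everywhere as `dissim(a, b)`: descriptors of a
#' reference shape ensemble are z-scored (zero-variance descriptors dropped
#' with a message), projected onto the top `d` principal components, and the
#' projection is rescaled so that the root-mean-square pairwise distance over
#' the reference ensemble equals exactly 2.0. That pinned unit makes the
#' magnitude and similarity constants of the factorial design interpretable
#' as distances in this space. The fit is deterministic given the ensemble
#' and `d`.
#'
#' @param reference_shapes list of [contour()]s (intended >= 1000).
#' @param d embedding dimensionality (default 22).
#' @param n_points descriptor resampling resolution.
#' @param orientation_sensitive keep the rotation-sensitive descriptors
#'   (default `TRUE`; a space fitted with `FALSE` cannot detect rotations).
#' @return an object of class `shape_space`.
#' @export
fit_shape_space <- function(reference_shapes, d = 22L, n_points = 100L,
                            orientation_sensitive = TRUE) {
  N <- length(reference_shapes)
  if (N <= d) stop("need more reference shapes than embedding dimensions")
  if (N < 1000)
    warning(sprintf("reference ensemble has %d shapes; >= 1000 recommended", N))
  X <- t(vapply(reference_shapes, shape_descriptors, numeric(37),
                n_points = n_points))
  if (!orientation_sensitive)
    X <- X[, setdiff(colnames(X), orientation_descriptor_names()), drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 1e-10
  if (!any(keep)) stop("all descriptors have zero variance on this ensemble")
  if (any(!keep))
    message("dropping zero-variance descriptors: ",
            paste(colnames(X)[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  mu <- colMeans(X)
  sdv <- sds[keep]
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  d <- min(as.integer(d), ncol(Z))
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(d), drop = FALSE]
  # pin component signs so refits are reproducible across platforms
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2, flip, "*")
  Y <- Z %*% rot
  msq <- 2 * sum(Y^2) / (N - 1)           # mean squared pairwise distance
  s <- 2 / sqrt(msq)
  structure(list(
    roster_version = descriptor_roster_version,
    descriptor_names = colnames(X),
    means = mu, sds = sdv,
    projection = rot * s,
    d = d, n_points = as.integer(n_points),
    unit_scale = s, n_reference = N,
    orientation_sensitive = orientation_sensitive
  ), class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf(
    "<shape_space %s: %d descriptors -> %d dims, %d reference shapes, unit RMS=2>\n",
    x$roster_version, length(x$descriptor_names), x$d, x$n_reference))
  invisible(x)
}

#' Embed a contour into a fitted shape space
#'
#' @param space a [fit_shape_space()] result.
#' @param c a [contour()].
#' @return numeric vector of length `space$d`.
#' @export
embed_contour <- function(space, c) {
  v <- shape_descriptors(as_contour(c), n_points = space$n_points)
  v <- v[space$descriptor_names]
  as.vector(((v - space$means) / space$sds) %*% space$projection)
}

#' Perceptual dissimilarity between two contours
#'
#' Euclidean distance between the embedded descriptor vectors of the two
#' normalized contours. Normalization performs the center matching, so the
#' distance is invariant to translation and uniform scaling, symmetric, and
#' zero for identical shapes; it is sensitive to rotation by construction.
#'
#' @param a,b [contour()]s.
#' @param space a fitted [fit_shape_space()].
#' @return a nonnegative number, in the space's similarity units.
#' @export
dissim <- function(a, b, space) {
  sqrt(sum((embed_contour(space, a) - embed_contour(space, b))^2))
}

#' 2D neighbor-embedding projection for visualization
#'
#' Projects a collection of shapes to 2D with t-distributed stochastic
#' neighbor embedding run on their embedded coordinates. Deterministic given
#' `seed`. Intended for visual inspection of where drawings fall relative to
#' test and transformed-test anchors; not used by any statistic.
#'
#' @param shapes list of [contour()]s (>= 5).
#' @param space a fitted [fit_shape_space()].
#' @param seed integer seed for the embedding initialization.
#' @param perplexity t-SNE perplexity; capped at `(n - 1) / 3`.
#' @param n_iter gradient-descent iterations.
#' @return an n x 2 matrix of coordinates, one row per shape.
#' @export
project_2d <- function(shapes, space, seed = 1L, perplexity = 10, n_iter = 400L) {
  if (length(shapes) < 5) stop("need at least 5 shapes to project")
  Y <- t(vapply(shapes, function(s) embed_contour(space, s),
                numeric(space$d)))
  tsne_embed(Y, seed = seed, perplexity = perplexity, n_iter = n_iter)
}

# Compact exact t-SNE (symmetric SNE with Student-t low-dimensional kernel),
# adequate for the few hundred shapes a stimulus set contains.
tsne_embed <- function(X, seed = 1L, perplexity = 10, n_iter = 400L) {
  n <- nrow(X)
  perplexity <- max(2, min(perplexity, (n - 1) / 3))
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Yl <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  inc <- matrix(0, n, 2)
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 4 else 1
    sumY <- rowSums(Yl^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Yl))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Yl
    mom <- if (it <= 50) 0.5 else 0.8
    inc <- mom * inc - 100 * grad
    Yl <- Yl + inc
    Yl <- sweep(Yl, 2, colMeans(Yl))
  }
  colnames(Yl) <- c("x", "y")
  Yl
}
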