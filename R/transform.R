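#' Parametric contour deformations
#'
#' Five one-parameter deformation fields acting on normalized coordinates:
#' `rotation`, `shear`, `twist`, `bloat` and `fisheye`. Each is the identity
#' at zero magnitude. With `R = sqrt(2)/2` (the half-diagonal of the unit
#' bounding box), `r = |p|` and `theta = atan2(y, x)`:
#'
#' * rotation: rotate about the origin by `m` (radians, positive =
#'   counterclockwise in stored y-up coordinates, i.e. clockwise on a y-down
#'   canvas).
#' * shear: `(x + m * y, y)`.
#' * twist: rotate by `m * (1 - r / R)`, maximal at the center and zero at
#'   radius `R` (clamped to zero beyond), so the outer boundary stays
#'   anchored.
#' * bloat: radial map `r -> R * (r / R)^(1 / (1 + m))`, `m >= 0`; angles
#'   preserved.
#' * fisheye: radial map `r -> R * tanh(m * r / R) / tanh(m)`, `m > 0`;
#'   angles preserved; the `m -> 0` limit is the identity.
#'
#' @param kind one of `"twist"`, `"bloat"`, `"fisheye"`, `"shear"`,
#'   `"rotation"`.
#' @param raw_param magnitude `m` (radians for twist/rotation, dimensionless
#'   otherwise).
#' @param p matrix of points (n x 2) in normalized coordinates.
#' @return matrix of transformed points, same shape as `p`.
#' @export
displacement_field <- function(kind, raw_param, p) {
  kind <- match.arg(kind, transform_kinds())
  p <- matrix(as.numeric(p), ncol = 2)
  m <- raw_param
  R <- sqrt(2) / 2
  if (kind %in% c("bloat", "fisheye") && m < 0)
    stop(sprintf("%s magnitude must be nonnegative, got %g", kind, m))
  switch(kind,
    rotation = rotate_points(p, m),
    shear = cbind(p[, 1] + m * p[, 2], p[, 2]),
    twist = {
      r <- sqrt(rowSums(p^2))
      ang <- m * pmax(0, 1 - r / R)
      cbind(cos(ang) * p[, 1] - sin(ang) * p[, 2],
            sin(ang) * p[, 1] + cos(ang) * p[, 2])
    },
    bloat = {
      r <- sqrt(rowSums(p^2))
      fac <- ifelse(r > 0, R * (r / R)^(1 / (1 + m)) / r, 0)
      p * fac
    },
    fisheye = {
      if (m < 1e-9) return(p)
      r <- sqrt(rowSums(p^2))
      fac <- ifelse(r > 0, R * tanh(m * r / R) / (tanh(m) * r), 0)
      p * fac
    }
  )
}

#' @export
transform_kinds <- function() c("twist", "bloat", "fisheye", "shear", "rotation")

#' Transformation specification
#'
#' Bundles a deformation kind with its raw magnitude parameter and the
#' similarity-space distance it was calibrated to produce. `raw_param = 0`
#' always yields the identity map.
#'
#' @param kind one of [transform_kinds()].
#' @param raw_param magnitude parameter.
#' @param target_units desired similarity-space distance (calibration target),
#'   or `NA` when the spec was set directly.
#' @param calibrated_units distance actually achieved on the calibration
#'   shape, or `NA`.
#' @return an object of class `transform_spec`.
#' @export
transform_spec <- function(kind, raw_param, target_units = NA_real_,
                           calibrated_units = NA_real_) {
  kind <- match.arg(kind, transform_kinds())
  structure(list(kind = kind, raw_param = as.numeric(raw_param),
                 target_units = as.numeric(target_units),
                 calibrated_units = as.numeric(calibrated_units)),
            class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat(sprintf("<transform_spec: %s, raw=%.5g, target=%.3g, achieved=%.3g>\n",
              x$kind, x$raw_param, x$target_units, x$calibrated_units))
  invisible(x)
}

#' Apply a deformation to a contour
#'
#' Maps every vertex through [displacement_field()]; for every kind except
#' rotation the result is re-normalized to the unit box (rotation is left
#' un-rescaled so that its effect is purely rigid); for twist only, the
#' result is additionally Procrustes-rotated back onto the input contour so
#' that the rigid part of the twirl is discounted. Point count and index
#' correspondence are preserved.
#'
#' @param c a normalized, uniformly resampled [contour()].
#' @param spec a [transform_spec()].
#' @return the transformed `contour`.
#' @export
apply_transform <- function(c, spec) {
  p <- as_contour(c)
  if (spec$raw_param == 0) return(p)   # exact identity at zero magnitude
  out <- displacement_field(spec$kind, spec$raw_param, p)
  out <- contour(out, meta = attr(p, "meta"))
  if (spec$kind != "rotation") out <- normalize_contour(out)
  if (spec$kind == "twist") {
    out <- procrustes_rotate(out, p)
    attr(out, "procrustes_angle") <- NULL
  }
  out
}

#' Calibrate a transformation magnitude to a target similarity distance
#'
#' Finds the raw magnitude parameter at which the deformation moves shape `c`
#' a given distance in the similarity space, i.e. solves
#' `dissim(c, apply_transform(c, spec)) = target_units` in `raw_param`.
#' The distance is bracketed on a coarse grid over `bracket` and refined by
#' bisection to within `tol` similarity units. If the distance profile is not
#' monotone over the bracket (possible for rotation on near-symmetric
#' shapes), calibration falls back to a dense 512-point grid search and
#' returns the magnitude minimizing the deviation from the target.
#'
#' @param c the shape to calibrate on (normalized, uniformly resampled).
#' @param kind one of [transform_kinds()].
#' @param target_units target distance in similarity units (> 0).
#' @param space a fitted embedding space (see [fit_shape_space()]).
#' @param bracket search interval for `raw_param`.
#' @param tol calibration tolerance in similarity units.
#' @return a [transform_spec()] with `calibrated_units` recording the
#'   achieved distance.
#' @export
calibrate_magnitude <- function(c, kind, target_units, space,
                                bracket = c(0, 4), tol = 0.01) {
  stopifnot(target_units > 0)
  p <- as_contour(c)
  base <- embed_contour(space, p)
  f <- function(m) {
    tc <- apply_transform(p, transform_spec(kind, m))
    sqrt(sum((embed_contour(space, tc) - base)^2))
  }
  # bisection between a bracketing pair (f(lo) < target <= f(hi));
  # returns c(m, f(m))
  m_res <- diff(bracket) / 1024   # parameter resolution of the search
  bisect <- function(lo, hi, fhi) {
    m <- hi; fm <- fhi
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      fmid <- f(mid)
      if (abs(fmid - target_units) <= abs(fm - target_units)) {
        m <- mid; fm <- fmid
      }
      if ((abs(fmid - target_units) <= tol / 2 && (hi - lo) <= m_res) ||
          (hi - lo) < 1e-9) break
      if (fmid < target_units) lo <- mid else hi <- mid
    }
    c(m, fm)
  }
  grid <- seq(bracket[1], bracket[2], length.out = 17)[-1]
  vals <- vapply(grid, f, numeric(1))
  k <- which(vals >= target_units)
  if (length(k)) {
    hi <- grid[k[1]]
    lo <- if (k[1] == 1) bracket[1] else grid[k[1] - 1]
    res <- bisect(lo, hi, vals[k[1]])
    m <- res[1]; achieved <- res[2]
  } else {
    achieved <- Inf   # force the dense fallback below
    m <- NA_real_
  }
  if (!is.finite(achieved) || abs(achieved - target_units) > tol) {
    # non-monotone or discontinuous distance profile: dense grid search for
    # the argmin, then local bisection between the flanking grid points
    dense <- seq(bracket[1] + diff(bracket) / 512, bracket[2], length.out = 512)
    dvals <- vapply(dense, f, numeric(1))
    j <- which.min(abs(dvals - target_units))
    m <- dense[j]; achieved <- dvals[j]
    if (abs(achieved - target_units) > tol / 2) {
      lo_j <- max(1, j - 1); hi_j <- min(512, j + 1)
      pair <- NULL
      if ((dvals[lo_j] - target_units) * (dvals[j] - target_units) <= 0)
        pair <- c(dense[lo_j], dense[j], dvals[j])
      else if ((dvals[j] - target_units) * (dvals[hi_j] - target_units) <= 0)
        pair <- if (dvals[j] < target_units) c(dense[j], dense[hi_j], dvals[hi_j])
                else c(dense[hi_j], dense[j], dvals[j])
      if (!is.null(pair)) {
        res <- bisect(pair[1], pair[2], pair[3])
        if (abs(res[2] - target_units) < abs(achieved - target_units)) {
          m <- res[1]; achieved <- res[2]
        }
      }
    }
    if (max(dvals) < target_units - tol)
      stop_calibration(sprintf(
        "target %.3f units unreachable for %s within raw_param <= %g (best achievable %.3f)",
        target_units, kind, bracket[2], max(dvals)), best = max(dvals))
  }
  if (abs(achieved - target_units) > tol)
    stop_calibration(sprintf(
      "calibration for %s reached %.4f units, target %.3f (tolerance %.3g)",
      kind, achieved, target_units, tol), best = achieved)
  transform_spec(kind, m, target_units = target_units,
                 calibrated_units = achieved)
}
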