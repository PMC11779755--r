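#' Closed 2D contours
#'
#' A `contour` is an ordered sequence of (x, y) vertices describing a closed
#' polyline: the last point connects implicitly back to the first. Contours
#' are the universal shape representation in this package; stimuli, test
#' shapes and drawings are all contours.
#'
#' Coordinates are stored in mathematical convention (y up). The canonical
#' vertex order is clockwise as seen on a y-down drawing canvas, which
#' corresponds to a positive shoelace signed area in stored coordinates;
#' constructors reverse the vertex order (keeping the first vertex first)
#' when handed the opposite orientation. Consecutive duplicate vertices are
#' dropped.
#'
#' @param points a numeric matrix or data frame with two columns (x, y), or a
#'   list of length-2 numeric vectors; at least 3 distinct vertices.
#' @param meta optional free-form label attached to the contour.
#' @return an object of class `contour`: a numeric matrix with columns
#'   `x`, `y` and attribute `meta`.
#' @examples
#' sq <- contour(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)))
#' contour_perimeter(sq)
#' @export
contour <- function(points, meta = NULL) {
  if (is.data.frame(points)) points <- as.matrix(points[, 1:2])
  if (is.list(points) && !is.matrix(points)) points <- do.call(rbind, points)
  points <- matrix(as.numeric(points), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  if (anyNA(points) || any(!is.finite(points)))
    stop("contour points must be finite numbers")
  # drop consecutive duplicates (including a repeated closing vertex)
  n <- nrow(points)
  if (n >= 2) {
    nxt <- c(2:n, 1L)
    dup <- rowSums(abs(points - points[nxt, , drop = FALSE])) == 0
    # dup[i] TRUE means point i equals its successor; keep the successor
    if (any(dup)) points <- points[!dup, , drop = FALSE]
  }
  if (nrow(points) < 3) stop("a contour needs at least 3 distinct points")
  if (shoelace_area(points) < 0) {
    n <- nrow(points)
    points <- points[c(1L, n:2L), , drop = FALSE]
  }
  structure(points, meta = meta, class = c("contour", "matrix"))
}

#' @export
print.contour <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<contour: %d points%s>\n", nrow(x),
              if (is.null(m)) "" else paste0(", ", format(m))))
  invisible(x)
}

as_contour <- function(x) {
  if (inherits(x, "contour")) x else contour(x)
}

# Shoelace signed area in stored (y-up) coordinates. Positive for the
# canonical orientation.
shoelace_area <- function(p) {
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2]) / 2
}

#' Polygon measurements
#'
#' Perimeter, enclosed area and area centroid of a closed contour, computed by
#' the shoelace formulas.
#'
#' @param c a [contour()].
#' @return `contour_perimeter` and `contour_area` return single numbers
#'   (area is unsigned); `contour_centroid` returns a length-2 vector.
#'   For contours whose enclosed area is numerically zero the centroid falls
#'   back to the vertex mean.
#' @export
contour_perimeter <- function(c) {
  p <- as_contour(c)
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  sum(sqrt(rowSums((p[nxt, , drop = FALSE] - p)^2)))
}

#' @rdname contour_perimeter
#' @export
contour_area <- function(c) abs(shoelace_area(as_contour(c)))

#' @rdname contour_perimeter
#' @param mode `"area"` for the polygon area centroid (default), `"vertex"`
#'   for the plain vertex mean.
#' @export
contour_centroid <- function(c, mode = c("area", "vertex")) {
  mode <- match.arg(mode)
  p <- as_contour(c)
  if (mode == "vertex") return(colMeans(p))
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  cross <- p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2]
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  cx <- sum((p[, 1] + p[nxt, 1]) * cross) / (6 * a)
  cy <- sum((p[, 2] + p[nxt, 2]) * cross) / (6 * a)
  c(cx, cy)
}

#' Uniform arc-length resampling
#'
#' Resamples a closed contour to `n` points equally spaced by arc length along
#' the closed polyline, starting at the contour's first vertex and preserving
#' the traversal direction. The perimeter of the result equals the input
#' perimeter up to the chord-shortening of resampling (exact when sample
#' points land on the original vertices).
#'
#' @param c a [contour()].
#' @param n number of output points (>= 3).
#' @return a `contour` with `n` points.
#' @export
resample_uniform <- function(c, n = 100L) {
  p <- as_contour(c)
  n <- as.integer(n)
  if (n < 3) stop("n must be at least 3")
  m <- nrow(p)
  nxt <- c(2:m, 1L)
  seg <- sqrt(rowSums((p[nxt, , drop = FALSE] - p)^2))
  perim <- sum(seg)
  if (perim <= 0) stop_degenerate("degenerate contour: zero perimeter")
  s <- c(0, cumsum(seg))              # arc length at each vertex, closed
  px <- c(p[, 1], p[1, 1])
  py <- c(p[, 2], p[1, 2])
  target <- perim * (0:(n - 1)) / n
  out <- cbind(
    stats::approx(s, px, xout = target, method = "linear", ties = "ordered")$y,
    stats::approx(s, py, xout = target, method = "linear", ties = "ordered")$y
  )
  contour(out, meta = attr(p, "meta"))
}

#' Normalize a contour to the unit box with centroid at the origin
#'
#' Shifts each coordinate axis by its minimum, scales both axes by the single
#' resulting maximum value (a shared divisor, so the aspect ratio is
#' preserved and the longer bounding-box side becomes 1), then translates the
#' shape so that its centroid sits at (0, 0). The result spans approximately
#' \eqn{[-0.5, 0.5]} in each coordinate; exactly so when the centroid
#' coincides with the bounding-box center.
#'
#' @param c a [contour()].
#' @param centroid `"area"` (polygon area centroid, default) or `"vertex"`.
#' @return a normalized `contour`.
#' @export
normalize_contour <- function(c, centroid = c("area", "vertex")) {
  centroid <- match.arg(centroid)
  p <- as_contour(c)
  mins <- apply(p, 2, min)
  q <- sweep(p, 2, mins)
  s <- max(q)
  if (s <= 0) stop_degenerate("degenerate contour: zero extent")
  q <- q / s
  ctr <- contour_centroid(contour(q, meta = attr(p, "meta")), mode = centroid)
  contour(sweep(q, 2, ctr), meta = attr(p, "meta"))
}

#' Optimal rigid rotation onto a reference (orthogonal Procrustes)
#'
#' Rotates `c` about the origin by the closed-form angle minimizing the sum of
#' squared distances to the corresponding points of `reference`. Rotation
#' only: no scaling, no reflection, no translation. Both contours must have
#' the same number of points with index correspondence.
#'
#' @param c contour to rotate.
#' @param reference target contour with the same point count.
#' @return `c` rotated; attribute `"procrustes_angle"` carries the angle
#'   (radians, counterclockwise in stored coordinates).
#' @export
procrustes_rotate <- function(c, reference) {
  p <- as_contour(c); q <- as_contour(reference)
  if (nrow(p) != nrow(q))
    stop("point-count mismatch: contours must share point correspondence")
  num <- sum(p[, 1] * q[, 2] - p[, 2] * q[, 1])
  den <- sum(p[, 1] * q[, 1] + p[, 2] * q[, 2])
  theta <- atan2(num, den)
  out <- rotate_points(p, theta)
  res <- contour(out, meta = attr(p, "meta"))
  attr(res, "procrustes_angle") <- theta
  res
}

rotate_points <- function(p, theta) {
  ct <- cos(theta); st <- sin(theta)
  cbind(ct * p[, 1] - st * p[, 2], st * p[, 1] + ct * p[, 2])
}

#' Closure check for raw drawn traces
#'
#' A drawn trace counts as closed when the Euclidean distance between its
#' first and last points is strictly below `gap_threshold` (the drawing UI's
#' green-light criterion). The default threshold is 10 units on a
#' 2048 x 2048 abstract canvas.
#'
#' @param points raw point sequence (matrix or data frame, >= 2 rows) in
#'   canvas units.
#' @param gap_threshold maximum allowed endpoint gap, canvas units.
#' @return `TRUE` or `FALSE`.
#' @export
is_closed <- function(points, gap_threshold = 10) {
  p <- as.matrix(points)
  if (nrow(p) < 2) stop("need at least 2 points")
  gap <- sqrt(sum((p[nrow(p), 1:2] - p[1, 1:2])^2))
  gap < gap_threshold
}

#' Self-intersection test
#'
#' Brute-force proper-intersection test over all non-adjacent edge pairs of
#' the closed polyline. Touching at shared endpoints does not count.
#'
#' @param c a [contour()].
#' @return `TRUE` if the polygon is simple (no self-intersections).
#' @export
is_simple_polygon <- function(c) {
  p <- as_contour(c)
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  a1 <- p; a2 <- p[nxt, , drop = FALSE]
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  adj <- (j - i == 1) | (i == 1 & j == n)   # adjacent edges share a vertex
  i <- i[!adj]; j <- j[!adj]
  if (!length(i)) return(TRUE)
  ccw <- function(a, b, c)
    (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c[, 1] - a[, 1])
  p1 <- a1[i, , drop = FALSE]; p2 <- a2[i, , drop = FALSE]
  q1 <- a1[j, , drop = FALSE]; q2 <- a2[j, , drop = FALSE]
  d1 <- ccw(p1, p2, q1); d2 <- ccw(p1, p2, q2)
  d3 <- ccw(q1, q2, p1); d4 <- ccw(q1, q2, p2)
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}
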