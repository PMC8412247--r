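#' Segmented cell-boundary polyline
#'
#' Wraps one frame of a segmented boundary track: an ordered, closed polyline
#' of `M` two-dimensional points (micrometers). The contour must be simple
#' enough to have a well-defined orientation; positive (counter-clockwise)
#' orientation -- cell interior on the left -- is required. If the first and
#' last vertex coincide the duplicate closing vertex is dropped.
#'
#' @param points numeric matrix with `M >= 3` rows and columns `x`, `y`.
#' @param frame_index integer frame number (0-based), `>= 0`.
#' @param time acquisition time in seconds.
#' @return an object of class `contour_polyline` with elements `points`,
#'   `frame_index` and `time`.
#' @examples
#' sq <- contour_polyline(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' polygon_area(sq$points)  # 1
#' @export
contour_polyline <- function(points, frame_index = 0L, time = 0) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("`points` must have two columns (x, y)")
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n >= 4 && all(points[1, ] == points[n, ])) points <- points[-n, , drop = FALSE]
  n <- nrow(points)
  if (n < 3) stop("a contour polyline needs at least 3 distinct points")
  d <- sqrt(rowSums((points - points[c(2:n, 1), , drop = FALSE])^2))
  if (any(d == 0))
    stop("degenerate input: consecutive polyline points coincide")
  a <- polygon_area(points)
  if (a <= 0)
    stop("polyline is not positively oriented (signed area <= 0); ",
         "reverse the point order")
  structure(list(points = points, frame_index = as.integer(frame_index),
                 time = as.numeric(time)),
            class = "contour_polyline")
}

#' @export
print.contour_polyline <- function(x, ...) {
  cat(sprintf("<contour_polyline> frame %d, t = %g s, M = %d points\n",
              x$frame_index, x$time, nrow(x$points)))
  invisible(x)
}

#' Signed polygon area (surveyor's formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param points numeric matrix of vertices (closed implicitly).
#' @return signed enclosed area.
#' @export
polygon_area <- function(points) {
  n <- nrow(points)
  j <- c(2:n, 1)
  sum(points[, 1] * points[j, 2] - points[j, 1] * points[, 2]) / 2
}

#' Support angles from normalized secant length
#'
#' Maps the vertices of a closed polyline onto angles in `[0, 2*pi)`
#' proportionally to the cumulative secant (chord) length along the contour,
#' with the closing secant from the last back to the first vertex included in
#' the normalization. The first angle is always 0.
#'
#' @param points numeric matrix of `M >= 3` ordered 2D points, or a
#'   [contour_polyline()].
#' @return numeric vector of `M` strictly increasing angles starting at 0.
#' @examples
#' secant_support_angles(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' # 0, pi/2, pi, 3*pi/2 for the unit square
#' @export
secant_support_angles <- function(points) {
  if (inherits(points, "contour_polyline")) points <- points$points
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop("need at least 3 points")
  seg <- sqrt(rowSums((points[c(2:n, 1), , drop = FALSE] - points)^2))
  if (any(seg == 0))
    stop("degenerate input: consecutive polyline points coincide")
  total <- sum(seg)
  2 * pi * c(0, cumsum(seg[-n])) / total
}
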