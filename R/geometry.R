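#' Closed cell contour polygon
#'
#' A `contour_polygon` is a closed, simple polygon describing a single cell
#' outline. Vertices are stored "open" (the closing edge from the last vertex
#' back to the first is implicit) and re-oriented counterclockwise. The x axis
#' is the flow axis.
#'
#' @param x,y Numeric vertex coordinates (pixels or micrometres; the unit is
#'   carried by downstream calls, not by the object).
#' @param frame_index Optional 0-based frame index the contour was observed in.
#' @param timestamp Optional acquisition time in seconds
#'   (`frame_index / fps` by convention; no sub-frame interpolation).
#' @return An object of class `contour_polygon`.
#' @export
contour_polygon <- function(x, y, frame_index = NA_integer_, timestamp = NA_real_) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) >= 2 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]
    y <- y[-length(y)]
  }
  if (length(x) < 3) stop("a contour polygon needs at least 3 distinct vertices")
  if (.signed_area(x, y) < 0) { # enforce counterclockwise storage
    x <- rev(x)
    y <- rev(y)
  }
  structure(list(x = x, y = y, frame_index = frame_index, timestamp = timestamp),
            class = "contour_polygon")
}

#' @export
print.contour_polygon <- function(x, ...) {
  g <- .polygon_geometry(x$x, x$y)
  cat(sprintf("contour_polygon: %d vertices, area %.3g, perimeter %.3g\n",
              length(x$x), g$A, g$P))
  invisible(x)
}

## Shoelace signed area of an open polygon (positive = counterclockwise).
.signed_area <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

## Shoelace area, perimeter and centroid in one pass.
.polygon_geometry <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  A <- sum(cross) / 2
  if (abs(A) < .Machine$double.eps * max(1, max(abs(x)), max(abs(y)))^2)
    stop("degenerate (zero-area) polygon")
  cx <- sum((x + xn) * cross) / (6 * A)
  cy <- sum((y + yn) * cross) / (6 * A)
  P <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  list(A = abs(A), P = P, com = c(cx, cy))
}

#' Area, perimeter and center-of-mass of a cell contour
#'
#' Computes the shoelace area, the polygonal perimeter and the polygon
#' centroid of a contour, scaled from pixels to micrometres.
#'
#' @param contour A [contour_polygon] (or anything with `$x`, `$y` vertices).
#' @param pixel_size_um Pixel pitch in micrometres per pixel; use 1 if the
#'   contour is already in micrometres.
#' @return A list with `A` (area, µm²), `P` (perimeter, µm) and `com`
#'   (centroid `c(x, y)` in µm).
#' @examples
#' sq <- contour_polygon(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' measure_geometry(sq, pixel_size_um = 1) # A = 1, P = 4, com = (0.5, 0.5)
#' @export
measure_geometry <- function(contour, pixel_size_um = 1) {
  stopifnot(pixel_size_um > 0)
  g <- .polygon_geometry(contour$x, contour$y)
  list(A = g$A * pixel_size_um^2,
       P = g$P * pixel_size_um,
       com = g$com * pixel_size_um)
}

#' Deformation (1 - circularity) of a shape
#'
#' Deformation is defined through the circularity \eqn{c = 2\sqrt{\pi A}/P}:
#' \eqn{d = 1 - c}. It is zero for a circle and positive for any other shape.
#' Values marginally below zero caused by pixel discretization are clipped
#' to 0.
#'
#' @param shape A [contour_polygon], a [reconstructed_contour], or a list with
#'   fields `A` and `P`.
#' @return Deformation `d`, dimensionless, `>= 0`.
#' @export
deformation <- function(shape) UseMethod("deformation")

#' @export
deformation.contour_polygon <- function(shape) {
  g <- .polygon_geometry(shape$x, shape$y)
  .deformation_from_AP(g$A, g$P)
}

#' @export
deformation.reconstructed_contour <- function(shape) shape$d

#' @export
deformation.default <- function(shape) {
  if (is.list(shape) && !is.null(shape$A) && !is.null(shape$P))
    return(.deformation_from_AP(shape$A, shape$P))
  stop("cannot compute deformation for this object")
}

.deformation_from_AP <- function(A, P) {
  if (!is.finite(A) || !is.finite(P) || A <= 0 || P <= 0)
    stop("degenerate geometry: need A > 0 and P > 0")
  max(0, 1 - 2 * sqrt(pi * A) / P)
}

#' Convex hull of a contour
#'
#' Replaces a contour by its convex hull, preserving frame index and
#' timestamp. Cell contours are convex by assumption; the hull step makes the
#' shape measures robust to single-vertex segmentation jitter.
#'
#' @param contour A [contour_polygon].
#' @return A [contour_polygon] on the hull vertices, counterclockwise.
#' @export
convex_hull <- function(contour) {
  h <- grDevices::chull(contour$x, contour$y) # clockwise order
  h <- rev(h)
  contour_polygon(contour$x[h], contour$y[h],
                  frame_index = contour$frame_index,
                  timestamp = contour$timestamp)
}
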