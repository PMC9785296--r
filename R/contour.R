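#' Closed pronotum contour
#'
#' Constructs a closed pseudolandmark contour from an ordered set of (x, y)
#' coordinates. The contour is stored open-ended: the first point is *not*
#' repeated at the end, closure is implicit. On construction the traversal
#' direction is recorded; use [enforce_orientation()] to force the
#' counterclockwise convention expected by the elliptic Fourier routines.
#'
#' @param points two-column numeric matrix (or data frame) of x, y
#'   coordinates, ordered along the outline. Units are micrometres by
#'   convention, carried at the dataset level.
#' @return An object of class `pronotum_contour`: the coordinate matrix with
#'   an `orientation` attribute (`"ccw"` or `"cw"`).
#' @examples
#' sq <- contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1) * 10 + 1))
#' @export
contour <- function(points) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2L)
    stop("contour points must be a two-column numeric matrix")
  if (anyNA(pts) || any(!is.finite(pts)))
    stop("contour points must be finite")
  n <- nrow(pts)
  if (n < 8L)
    stop("a contour needs at least 8 points, got ", n)
  # drop an explicitly repeated closing point
  if (isTRUE(all.equal(pts[1L, ], pts[n, ], tolerance = 0,
                       check.attributes = FALSE))) {
    pts <- pts[-n, , drop = FALSE]
    n <- n - 1L
    if (n < 8L) stop("a contour needs at least 8 points after de-closing")
  }
  nxt <- c(2:n, 1L)
  dup <- rowSums((pts[nxt, , drop = FALSE] - pts)^2) == 0
  if (any(dup))
    stop("consecutive duplicate points at positions: ",
         paste(which(dup), collapse = ", "))
  dimnames(pts) <- list(NULL, c("x", "y"))
  structure(pts,
            orientation = if (signed_area(pts) >= 0) "ccw" else "cw",
            class = "pronotum_contour")
}

#' @export
print.pronotum_contour <- function(x, ...) {
  cat(sprintf("Closed contour: %d points, %s, area %.4g\n",
              nrow(x), attr(x, "orientation"), abs(signed_area(x))))
  invisible(x)
}

#' @export
plot.pronotum_contour <- function(x, ..., asp = 1, type = "l") {
  xy <- rbind(unclass(x), unclass(x)[1L, , drop = FALSE])
  graphics::plot(xy, asp = asp, type = type, xlab = "x", ylab = "y", ...)
  invisible(x)
}

#' Signed polygon area (shoelace formula)
#'
#' Positive for counterclockwise traversal in a y-up frame.
#'
#' @param pts two-column coordinate matrix, implicitly closed.
#' @return signed area.
#' @export
signed_area <- function(pts) {
  pts <- unclass(as.matrix(pts))
  n <- nrow(pts)
  nxt <- c(2:n, 1L)
  sum(pts[, 1L] * pts[nxt, 2L] - pts[nxt, 1L] * pts[, 2L]) / 2
}

#' Force counterclockwise traversal
#'
#' Reverses the point order of a clockwise contour so that the signed area is
#' positive, keeping the starting point in place. Counterclockwise input is
#' returned unchanged.
#'
#' @param x a [contour()].
#' @param tol contours whose |signed area| falls below `tol` relative to the
#'   squared coordinate scale are rejected as degenerate.
#' @return the contour, counterclockwise.
#' @export
enforce_orientation <- function(x, tol = 1e-10) {
  stopifnot(inherits(x, "pronotum_contour"))
  a <- signed_area(x)
  scale2 <- max(apply(unclass(x), 2L, function(v) diff(range(v))))^2
  if (abs(a) <= tol * max(scale2, .Machine$double.eps))
    stop("degenerate contour: |signed area| below tolerance")
  if (a > 0) return(x)
  pts <- unclass(x)
  n <- nrow(pts)
  contour(pts[c(1L, n:2L), , drop = FALSE])
}

## perimeter of the implicitly closed polygon
contour_perimeter <- function(x) {
  pts <- unclass(as.matrix(x))
  n <- nrow(pts)
  nxt <- c(2:n, 1L)
  sum(sqrt(rowSums((pts[nxt, , drop = FALSE] - pts)^2)))
}

#' Apply a rigid motion plus scaling to a contour
#'
#' Convenience for invariance checks: rotates by `angle` (radians,
#' counterclockwise), scales by `scale`, then translates by `shift`.
#' Optionally restarts the contour at point index `start`.
#'
#' @param x a [contour()].
#' @param angle rotation angle in radians.
#' @param scale positive scale factor.
#' @param shift length-2 translation.
#' @param start new starting index (1-based) along the point sequence.
#' @return a transformed [contour()].
#' @export
transform_contour <- function(x, angle = 0, scale = 1, shift = c(0, 0),
                              start = 1L) {
  stopifnot(inherits(x, "pronotum_contour"), scale > 0)
  pts <- unclass(x)
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  pts <- scale * pts %*% t(R)
  pts <- sweep(pts, 2L, -as.numeric(shift))
  n <- nrow(pts)
  start <- ((as.integer(start) - 1L) %% n) + 1L
  if (start != 1L) pts <- pts[c(start:n, seq_len(start - 1L)), , drop = FALSE]
  contour(pts)
}
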