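# Planar polygon primitives: area, centroid, orientation, simplicity,
# and radius-at-angle sampling for star-shaped contours. Contours are
# n x 2 matrices of (x, y) vertices in mm, closed implicitly (last
# vertex connects back to the first).

as_polygon <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  stop_if(!is.matrix(p) || ncol(p) != 2 || !is.numeric(p),
          "a contour must be an n x 2 numeric matrix of (x, y) vertices")
  stop_if(anyNA(p) || any(!is.finite(p)), "contour vertices must be finite")
  # drop an explicitly repeated closing vertex
  n <- nrow(p)
  if (n > 1 && all(p[1, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  stop_if(nrow(p) < 3, "a closed contour needs at least 3 distinct vertices")
  unname(p)
}

# Signed area by the shoelace formula; positive for CCW orientation.
polygon_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Cross-sectional area of a closed contour
#'
#' Shoelace (surveyor's) formula; the absolute value is returned so the
#' result is independent of vertex orientation. This is the area entering
#' the disc-summation volume of a short-axis slice.
#'
#' @param polygon n x 2 numeric matrix of (x, y) vertices in mm, n >= 3.
#' @return area in mm^2.
#' @examples
#' contour_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
contour_area <- function(polygon) {
  abs(polygon_signed_area(as_polygon(polygon)))
}

#' Area-weighted centroid of a closed contour
#'
#' Standard polygon-centroid formula (first moments of the enclosed
#' region over its area). The centroid of the end-diastolic endocardial
#' contour defines the origin for radial displacement sampling.
#'
#' @inheritParams contour_area
#' @return length-2 numeric vector (x, y) in mm.
#' @examples
#' contour_centroid(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # (0.5, 0.5)
#' @export
contour_centroid <- function(polygon) {
  p <- as_polygon(polygon)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  w <- x * yn - xn * y
  a <- sum(w) / 2
  stop_if(abs(a) < .Machine$double.eps * max(abs(p)) * nrow(p) + 1e-300,
          "degenerate (zero-area) contour has no centroid")
  c(sum((x + xn) * w), sum((y + yn) * w)) / (6 * a)
}

# Reorder vertices to counterclockwise orientation (reversal if needed).
ensure_ccw <- function(p) {
  if (polygon_signed_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

# TRUE if the closed polygon has no properly crossing edge pair and no
# zero-length edges. O(n^2) vectorized orientation tests; adjacent edges
# (sharing a vertex) are exempt.
polygon_is_simple <- function(p) {
  n <- nrow(p)
  px <- p[, 1]; py <- p[, 2]
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  if (any(px == qx & py == qy)) return(FALSE)
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  adjacent <- (j - i == 1L) | (i == 1L & j == n)
  i <- i[!adjacent]; j <- j[!adjacent]
  if (!length(i)) return(TRUE)
  o <- function(ax, ay, bx, by, cx, cy) {
    sign(cross2(bx - ax, by - ay, cx - ax, cy - ay))
  }
  o1 <- o(px[i], py[i], qx[i], qy[i], px[j], py[j])
  o2 <- o(px[i], py[i], qx[i], qy[i], qx[j], qy[j])
  o3 <- o(px[j], py[j], qx[j], qy[j], px[i], py[i])
  o4 <- o(px[j], py[j], qx[j], qy[j], qx[i], qy[i])
  proper <- (o1 * o2 < 0) & (o3 * o4 < 0)
  # collinear overlap counts as non-simple only if the segments touch
  touching <- (o1 == 0 & o2 == 0) &
    (pmin(px[i], qx[i]) <= pmax(px[j], qx[j]) &
     pmax(px[i], qx[i]) >= pmin(px[j], qx[j]) &
     pmin(py[i], qy[i]) <= pmax(py[j], qy[j]) &
     pmax(py[i], qy[i]) >= pmin(py[j], qy[j]))
  !any(proper | touching)
}

# Radius of a star-shaped contour along rays from `center` at `angles`
# (radians, CCW from +x). Exploits star-shapedness: vertex polar angles
# about the center must be CCW-monotone (one full turn); the ray at
# angle phi then meets exactly the edge whose angular interval brackets
# phi. Errors with `what` in the message when the contour is not
# star-shaped about the center or a ray has no positive intersection.
polygon_radii <- function(p, angles, center, what = "contour") {
  vx <- p[, 1] - center[1]
  vy <- p[, 2] - center[2]
  th <- atan2(vy, vx)
  n <- length(th)
  # rotate so the vertex sequence starts at its smallest angle, then
  # monotonicity over one turn is a plain sortedness check
  k <- which.min(th)
  ord <- c(k:n, seq_len(k - 1L))
  th <- th[ord]; vx <- vx[ord]; vy <- vy[ord]
  bad <- which(diff(th) <= 0)
  stop_if(length(bad) > 0,
          "%s is not star-shaped about the reference centroid (vertex angle reversal near %.1f deg)",
          what, th[bad[1]] * 180 / pi)
  # reduce each ray angle into [th[1], th[1] + 2*pi); findInterval then
  # picks the bracketing edge, with index n meaning the wrap edge n -> 1
  phi <- ((angles - th[1]) %% (2 * pi)) + th[1]
  edge <- findInterval(phi, th)
  a <- edge
  b <- ifelse(edge == n, 1L, edge + 1L)
  ux <- cos(angles); uy <- sin(angles)
  ex <- vx[b] - vx[a]; ey <- vy[b] - vy[a]
  den <- cross2(ux, uy, ex, ey)
  s <- -cross2(ux, uy, vx[a], vy[a]) / den
  r <- (vx[a] + s * ex) * ux + (vy[a] + s * ey) * uy
  bad <- !is.finite(r) | r <= 0
  stop_if(any(bad),
          "%s: ray at %.1f deg does not intersect the contour exactly once",
          what, angles[which(bad)[1]] * 180 / pi)
  r
}
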