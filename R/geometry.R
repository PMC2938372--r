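#' Polygon area by the shoelace formula
#'
#' Area (um^2) of a closed simple ring given as an n x 2 coordinate matrix
#' in counterclockwise order.  This realizes the current cell volume
#' \eqn{V_{cur}} used by the growth rules (a 2D "volume" is an area).
#'
#' @param ring n x 2 numeric matrix of vertices, counterclockwise, not
#'   repeating the first vertex.
#' @param signed if `TRUE` return the signed area (negative for clockwise
#'   input) instead of rejecting clockwise rings.
#' @return Positive area in um^2.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' polygon_area(sq)  # 1
#' @export
polygon_area <- function(ring, signed = FALSE) {
  if (!is.matrix(ring) || nrow(ring) < 3L)
    stop("ring must be a matrix with at least 3 vertices")
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- 0.5 * sum(x * yn - xn * y)
  if (signed) return(a)
  if (a <= 0)
    stop("ring is clockwise or degenerate; rings must be counterclockwise")
  a
}

ring_centroid <- function(ring) colMeans(ring)

#' Outward unit normal at a ring vertex
#'
#' The normal is perpendicular to the chord joining the vertex's two ring
#' neighbors and points away from the ring interior (for a
#' counterclockwise ring, the right-hand side of the chord direction).
#' Used to orient the osmotic pressure load and the short-range repulsion.
#'
#' @param ring n x 2 coordinate matrix, counterclockwise, n >= 3.
#' @param index 1-based vertex index (vectorized).
#' @return length(index) x 2 matrix of unit normals.
#' @export
outward_normal <- function(ring, index = seq_len(nrow(ring))) {
  n <- nrow(ring)
  if (is.null(n) || n < 3L) stop("ring must have at least 3 vertices")
  ip <- ((index - 2L) %% n) + 1L
  im <- (index %% n) + 1L
  cx <- ring[im, 1] - ring[ip, 1]
  cy <- ring[im, 2] - ring[ip, 2]
  len <- sqrt(cx * cx + cy * cy)
  if (any(len < 1e-12))
    stop("degenerate geometry: coincident ring neighbors (zero-length chord)")
  # CCW ring: rotate chord direction by -90 degrees for the outward side
  cbind(cy / len, -cx / len, deparse.level = 0)
}

#' Distance from a point to a closed segment
#'
#' Euclidean distance from `p` to the segment `a`--`b`, with the closest
#' point, realizing the surface distance entering the short-range
#' repulsion law.
#'
#' @param p length-2 point.
#' @param a,b segment endpoints (distinct).
#' @return list with `dist`, `closest` (length-2 point) and `t`, the
#'   barycentric coordinate of the closest point along `a`--`b`.
#' @export
point_segment_distance <- function(p, a, b) {
  e <- b - a
  L2 <- sum(e * e)
  if (L2 <= 0) stop("degenerate segment: identical endpoints")
  t <- sum((p - a) * e) / L2
  t <- min(1, max(0, t))
  cl <- a + t * e
  list(dist = sqrt(sum((p - cl)^2)), closest = cl, t = t)
}

# Does the closed ring self-intersect?  O(n^2) segment test; used by
# validators and tests, not in the inner loop.
ring_is_simple <- function(ring) {
  n <- nrow(ring)
  if (n < 3L) return(FALSE)
  seg <- cbind(ring, ring[c(2:n, 1L), ])
  ccw <- function(ax, ay, bx, by, cx, cy)
    (by - ay) * (cx - ax) - (bx - ax) * (cy - ay)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent segments (share a vertex)
      if (j == i + 1L || (i == 1L && j == n)) next
      a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[j, 1:2]; d <- seg[j, 3:4]
      d1 <- ccw(a[1], a[2], b[1], b[2], c[1], c[2])
      d2 <- ccw(a[1], a[2], b[1], b[2], d[1], d[2])
      d3 <- ccw(c[1], c[2], d[1], d[2], a[1], a[2])
      d4 <- ccw(c[1], c[2], d[1], d[2], b[1], b[2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

#' Even-odd point-in-polygon test
#'
#' Vectorized crossing test; used e.g. to verify that an acinar lumen is
#' cell-free.
#'
#' @param pts point matrix (n x 2) or a single length-2 point.
#' @param poly polygon vertex matrix.
#' @return logical vector: is each point inside the polygon?
#' @export
point_in_polygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Sutherland-Hodgman clipping of `subject` against a convex `clip`
# polygon (both CCW).  Returns the clipped polygon matrix (possibly with
# 0 rows).  Cells are near-convex, so this serves for the small pairwise
# overlap corrections in the occupied-area computation.
clip_polygon <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0L) break
    a <- clip[e, ]; b <- clip[(e %% nc) + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])  # >=0 inside (CCW)
    n <- nrow(out)
    nxt <- c(2:n, 1L)[seq_len(n)]
    if (n == 1L) nxt <- 1L
    keep <- list(); m <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      ci <- side[i] >= 0; cj <- side[j] >= 0
      if (ci) { m <- m + 1L; keep[[m]] <- out[i, ] }
      if (ci != cj) {
        t <- side[i] / (side[i] - side[j])
        m <- m + 1L
        keep[[m]] <- out[i, ] + t * (out[j, ] - out[i, ])
      }
    }
    out <- if (m == 0L) matrix(numeric(0), 0, 2) else do.call(rbind, keep)
  }
  out
}

# Area of overlap between two (near-)convex CCW polygons.
polygon_overlap_area <- function(p1, p2) {
  cl <- clip_polygon(p1, p2)
  if (nrow(cl) < 3L) return(0)
  abs(polygon_area(cl, signed = TRUE))
}
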