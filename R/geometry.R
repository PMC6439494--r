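# Planar polygon utilities for county maps.
#
# All geometry in resistgen lives in a single planar projection with meter
# units; nothing here reprojects. Polygons are numeric matrices with two
# columns (x, y), vertices in ring order, not explicitly closed. A county
# may be a multi-part polygon: a list of such rings, assumed disjoint.

#' Signed and absolute polygon area
#'
#' Shoelace formula on a single ring. `polygon_area()` returns the absolute
#' area in square meters.
#'
#' @param ring numeric matrix with columns x, y (vertices in order, open ring)
#' @return area in squared coordinate units
#' @keywords internal
polygon_area <- function(ring) {
  abs(signed_area(ring))
}

signed_area <- function(ring) {
  ring <- drop_closing_vertex(ring)
  n <- nrow(ring)
  if (n < 3) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

drop_closing_vertex <- function(ring) {
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  ring
}

ensure_ccw <- function(ring) {
  if (signed_area(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
}

is_convex_ring <- function(ring) {
  ring <- drop_closing_vertex(ring)
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  nxt <- c(seq(2L, n), 1L)
  nxt2 <- nxt[nxt]
  cr <- (ring[nxt, 1] - ring[, 1]) * (ring[nxt2, 2] - ring[nxt, 2]) -
        (ring[nxt, 2] - ring[, 2]) * (ring[nxt2, 1] - ring[nxt, 1])
  all(cr >= -1e-9 * max(abs(cr), 1)) || all(cr <= 1e-9 * max(abs(cr), 1))
}

ring_self_intersects <- function(ring) {
  ring <- drop_closing_vertex(ring)
  n <- nrow(ring)
  if (n < 4) return(FALSE)
  nxt <- c(seq(2L, n), 1L)
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next  # shared vertex with closing edge
      if (segments_cross(ring[i, ], ring[nxt[i], ], ring[j, ], ring[nxt[j], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, q1, q2) {
  d1 <- cross2(q2 - q1, p1 - q1)
  d2 <- cross2(q2 - q1, p2 - q1)
  d3 <- cross2(p2 - p1, q1 - p1)
  d4 <- cross2(p2 - p1, q2 - p1)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

#' Clip a polygon against a convex polygon (Sutherland-Hodgman)
#'
#' @param subject,clip rings (matrices); `clip` must be convex
#' @return clipped ring matrix (possibly with < 3 rows when empty)
#' @keywords internal
clip_polygon_convex <- function(subject, clip) {
  subject <- drop_closing_vertex(subject)
  clip <- ensure_ccw(drop_closing_vertex(clip))
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) < 3) break
    a <- clip[e, ]
    b <- clip[if (e == nc) 1L else e + 1L, ]
    inp <- out
    n <- nrow(inp)
    out <- matrix(numeric(0), ncol = 2)
    # inside = left of directed edge a->b (CCW clip polygon)
    side <- (b[1] - a[1]) * (inp[, 2] - a[2]) - (b[2] - a[2]) * (inp[, 1] - a[1])
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      ci <- side[i] >= 0; cj <- side[j] >= 0
      if (ci) out <- rbind(out, inp[i, ])
      if (xor(ci, cj)) {
        t <- side[i] / (side[i] - side[j])
        out <- rbind(out, inp[i, ] + t * (inp[j, ] - inp[i, ]))
      }
    }
  }
  out
}

#' Intersection area of two rings
#'
#' Exact Sutherland-Hodgman clipping when at least one ring is convex;
#' otherwise falls back to a grid estimate (logged). County polygons from the
#' synthetic landscape generator are rectangles, so the exact path is the
#' norm.
#'
#' @keywords internal
ring_intersection_area <- function(p, q, grid_n = 400L) {
  bp <- apply(drop_closing_vertex(p), 2, range)
  bq <- apply(drop_closing_vertex(q), 2, range)
  if (bp[2, 1] <= bq[1, 1] || bq[2, 1] <= bp[1, 1] ||
      bp[2, 2] <= bq[1, 2] || bq[2, 2] <= bp[1, 2]) {
    return(0)
  }
  if (is_convex_ring(q)) return(polygon_area(clip_polygon_convex(p, q)))
  if (is_convex_ring(p)) return(polygon_area(clip_polygon_convex(q, p)))
  message("ring_intersection_area: neither ring convex; using grid estimate")
  grid_intersection_area(p, q, grid_n)
}

#' Grid (rasterization) estimate of ring intersection area
#' @keywords internal
grid_intersection_area <- function(p, q, grid_n = 400L) {
  lo <- pmax(apply(drop_closing_vertex(p), 2, min), apply(drop_closing_vertex(q), 2, min))
  hi <- pmin(apply(drop_closing_vertex(p), 2, max), apply(drop_closing_vertex(q), 2, max))
  if (any(hi <= lo)) return(0)
  xs <- seq(lo[1], hi[1], length.out = grid_n + 1L)
  ys <- seq(lo[2], hi[2], length.out = grid_n + 1L)
  cx <- (xs[-1] + xs[-length(xs)]) / 2
  cy <- (ys[-1] + ys[-length(ys)]) / 2
  pts <- cbind(rep(cx, times = grid_n), rep(cy, each = grid_n))
  inside <- points_in_ring(pts[, 1], pts[, 2], p) & points_in_ring(pts[, 1], pts[, 2], q)
  cell <- diff(xs[1:2]) * diff(ys[1:2])
  sum(inside) * cell
}

#' Vectorized ray-casting point-in-polygon test (boundary counts as inside)
#'
#' @param x,y point coordinates
#' @param ring polygon ring matrix
#' @return logical vector
#' @keywords internal
points_in_ring <- function(x, y, ring) {
  ring <- drop_closing_vertex(ring)
  n <- nrow(ring)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | points_on_ring(x, y, ring)
}

#' Distance-based boundary membership test
#' @keywords internal
points_on_ring <- function(x, y, ring, eps = 1e-9) {
  ring <- drop_closing_vertex(ring)
  n <- nrow(ring)
  scale <- max(abs(ring), 1)
  on <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    ax <- ring[j, 1]; ay <- ring[j, 2]
    bx <- ring[i, 1]; by <- ring[i, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / len2))
    d2 <- (x - (ax + t * dx))^2 + (y - (ay + t * dy))^2
    on <- on | d2 <= (eps * scale)^2
    j <- i
  }
  on
}

#' Parameter values where segment a->b crosses the edges of a ring
#'
#' Returns sorted t in [0, 1] (a at t = 0). Collinear overlaps contribute
#' the projected endpoints of the overlap.
#'
#' @keywords internal
segment_ring_ts <- function(a, b, ring) {
  ring <- drop_closing_vertex(ring)
  n <- nrow(ring)
  d <- b - a
  ts <- numeric(0)
  j <- n
  for (i in seq_len(n)) {
    p <- ring[j, ]; q <- ring[i, ]
    e <- q - p
    denom <- cross2(d, e)
    if (abs(denom) > 1e-14 * max(abs(d %o% e), 1)) {
      t <- cross2(p - a, e) / denom
      u <- cross2(p - a, d) / denom
      if (t > -1e-12 && t < 1 + 1e-12 && u > -1e-12 && u < 1 + 1e-12) {
        ts <- c(ts, min(1, max(0, t)))
      }
    } else if (abs(cross2(p - a, d)) <= 1e-9 * max(sum(abs(d)), 1)) {
      # collinear edge: project its endpoints onto the segment
      len2 <- sum(d * d)
      if (len2 > 0) {
        tp <- sum((p - a) * d) / len2
        tq <- sum((q - a) * d) / len2
        ts <- c(ts, min(1, max(0, tp)), min(1, max(0, tq)))
      }
    }
    j <- i
  }
  sort(unique(ts))
}

#' Validate planar (projected) coordinates
#'
#' Rejects coordinate sets that look like longitude/latitude degrees: the
#' pipeline contract is meters in one planar projection.
#' @keywords internal
check_planar_coords <- function(xy, what = "coordinates") {
  if (!all(is.finite(xy))) stop(what, ": non-finite coordinates", call. = FALSE)
  x <- xy[, 1]; y <- xy[, 2]
  if (all(abs(x) <= 360) && all(abs(y) <= 90)) {
    stop(what, " look like longitude/latitude degrees; resistgen requires a ",
         "planar projection in meters and never reprojects", call. = FALSE)
  }
  invisible(TRUE)
}
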