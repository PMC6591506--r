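# Low-level planar geometry helpers shared by the component library,
# DXF import and manufacturing-layer generation. All coordinates are
# micrometres unless a function says otherwise. Rings are n x 2 matrices,
# not closed (first point is not repeated at the end).

#' Signed polygon area (shoelace)
#'
#' Positive for counter-clockwise rings in the x-right / y-up device frame.
#'
#' @param ring An n x 2 numeric matrix of vertices (open ring).
#' @return Signed area in squared input units.
#' @keywords internal
ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ring_area <- function(ring) abs(ring_signed_area(ring))

#' Area of a polygon with holes
#' @param poly list with `outer` ring and `holes` (list of rings).
#' @keywords internal
poly_area <- function(poly) {
  a <- ring_area(poly$outer)
  for (h in poly$holes) a <- a - ring_area(h)
  a
}

ensure_ccw <- function(ring) {
  if (ring_signed_area(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
}

ensure_cw <- function(ring) {
  if (ring_signed_area(ring) > 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
}

#' Make a polygon-with-holes, normalising orientations (outer CCW, holes CW)
#' @keywords internal
make_poly <- function(outer, holes = list()) {
  list(outer = ensure_ccw(outer), holes = lapply(holes, ensure_cw))
}

#' Axis-aligned rectangle ring centred at (cx, cy)
#' @keywords internal
rect_ring <- function(cx, cy, w, h) {
  matrix(c(cx - w / 2, cy - h / 2,
           cx + w / 2, cy - h / 2,
           cx + w / 2, cy + h / 2,
           cx - w / 2, cy + h / 2), ncol = 2, byrow = TRUE)
}

#' Regular polygon approximation of a circle
#'
#' The vertex radius is inflated by the area-compensation factor
#' sqrt(2*pi/n / sin(2*pi/n)) so the n-gon's area equals pi*r^2 exactly;
#' an inscribed 32-gon would otherwise fall 0.64% short. True circle
#' parameters are carried separately where exactness matters (drill
#' files).
#'
#' @param n Number of vertices; 32 by default per the export contract.
#' @keywords internal
circle_ring <- function(cx, cy, r, n = 32L) {
  r_eff <- r * sqrt((2 * pi / n) / sin(2 * pi / n))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r_eff * cos(th), cy + r_eff * sin(th))
}

#' Rotate (degrees CCW about the origin) then translate a point matrix
#' @keywords internal
transform_points <- function(pts, position = c(0, 0), rotation = 0) {
  th <- rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- pts %*% t(R)
  out[, 1] <- out[, 1] + position[1]
  out[, 2] <- out[, 2] + position[2]
  out
}

#' Bounding box of a list of rings
#' @return c(xmin, ymin, xmax, ymax)
#' @keywords internal
rings_bbox <- function(rings) {
  all <- do.call(rbind, rings)
  c(min(all[, 1]), min(all[, 2]), max(all[, 1]), max(all[, 2]))
}

#' Even-odd point-in-ring test
#' @keywords internal
point_in_ring <- function(p, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((y[i] > p[2]) != (y[j] > p[2])) &&
        (p[1] < (x[j] - x[i]) * (p[2] - y[i]) / (y[j] - y[i]) + x[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# Proper-crossing test for two segments, used by the simplicity check.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Is a ring simple (no self-intersections, no repeated vertices)?
#'
#' O(n^2) pairwise test; rings here are small (32-gons and rectangles).
#' @keywords internal
ring_is_simple <- function(ring, tol = 1e-9) {
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  # repeated consecutive vertices
  nxt <- rbind(ring[-1, , drop = FALSE], ring[1, , drop = FALSE])
  if (any(sqrt(rowSums((ring - nxt)^2)) < tol)) return(FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (j == i + 1L || (i == 1L && j == n)) next  # adjacent edges share a vertex
      jn <- if (j == n) 1L else j + 1L
      if (segments_cross(ring[i, ], ring[i + 1L, ], ring[j, ], ring[jn, ])) return(FALSE)
    }
  }
  TRUE
}

#' Nearest point on a polyline to a query point
#'
#' Ties between equidistant segments resolve to the earliest segment in
#' path order.
#'
#' @param path n x 2 matrix of waypoints (n >= 2).
#' @param p length-2 point.
#' @return list(point, segment (index of the segment's first vertex),
#'   t (position along that segment in [0, 1]), distance)
#' @keywords internal
project_on_polyline <- function(path, p) {
  best <- NULL
  for (i in seq_len(nrow(path) - 1L)) {
    a <- path[i, ]; b <- path[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
    q <- a + t * ab
    d <- sqrt(sum((p - q)^2))
    if (is.null(best) || d < best$distance - 1e-12) {
      best <- list(point = q, segment = i, t = t, distance = d)
    }
  }
  best
}

polyline_length <- function(path) {
  d <- diff(path)
  sum(sqrt(rowSums(d^2)))
}

# ---- polygon union (Clipper via polyclip) --------------------------------

ring_to_pc <- function(ring) list(x = ring[, 1], y = ring[, 2])
pc_to_ring <- function(pc) cbind(pc$x, pc$y)

#' Union a list of polygons-with-holes into disjoint polygons-with-holes
#'
#' Clipping runs at a fixed spatial resolution of 1e-6 um, far below any
#' feature size, so flush-joined rectangles union to their exact combined
#' area.
#'
#' @param polys list of `make_poly()` objects.
#' @return list of `make_poly()` objects covering the same region with
#'   no overlapping duplicates.
#' @keywords internal
union_polys <- function(polys) {
  if (length(polys) == 0) return(list())
  as_pc <- function(poly) c(list(ring_to_pc(poly$outer)), lapply(poly$holes, ring_to_pc))
  acc <- as_pc(polys[[1]])
  for (p in polys[-1]) {
    acc <- polyclip::polyclip(acc, as_pc(p), op = "union",
                              fillA = "nonzero", fillB = "nonzero",
                              eps = 1e-6)
  }
  rings <- lapply(acc, pc_to_ring)
  rings_to_polys(rings)
}

#' Group a flat set of rings into polygons with holes by containment parity
#' @keywords internal
rings_to_polys <- function(rings) {
  if (length(rings) == 0) return(list())
  n <- length(rings)
  depth <- integer(n)
  for (i in seq_len(n)) {
    p <- rings[[i]][1, ]
    for (j in seq_len(n)) {
      if (i != j && point_in_ring(p, rings[[j]])) depth[i] <- depth[i] + 1L
    }
  }
  outers <- which(depth %% 2L == 0L)
  polys <- lapply(outers, function(i) list(outer = rings[[i]], holes = list()))
  for (i in which(depth %% 2L == 1L)) {
    # attach to the smallest enclosing outer ring
    enc <- outers[vapply(outers, function(j) point_in_ring(rings[[i]][1, ], rings[[j]]),
                         logical(1))]
    if (length(enc) == 0) next
    areas <- vapply(enc, function(j) ring_area(rings[[j]]), numeric(1))
    k <- match(enc[which.min(areas)], outers)
    polys[[k]]$holes <- c(polys[[k]]$holes, list(rings[[i]]))
  }
  lapply(polys, function(p) make_poly(p$outer, p$holes))
}
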