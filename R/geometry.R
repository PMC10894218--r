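# Planar geometry kernel.
#
# All tessellation machinery in this package works on a minimal polygon
# representation: a "ring" is an n x 2 numeric matrix of vertices (not
# closed: last vertex != first, edges are cyclic), oriented
# counter-clockwise; a "geom" is a list of one or more disjoint-interior
# rings (a multipart polygon). Coordinates are in a projected CRS (metres).
# Rings produced by the Voronoi routines are convex; the predicates below
# (area, containment, shared-boundary length) do not require convexity,
# the clipping-based ones (intersection area, offsets) do and say so.

# signed area, positive for counter-clockwise rings
ring_signed_area <- function(ring) {
  n <- nrow(ring)
  if (n < 3) return(0)
  x <- ring[, 1L]; y <- ring[, 2L]
  nx <- c(2:n, 1L)
  sum(x * y[nx] - x[nx] * y) / 2
}

ring_area <- function(ring) abs(ring_signed_area(ring))

geom_area <- function(geom) sum(vapply(geom, ring_area, numeric(1)))

ring_centroid <- function(ring) {
  n <- nrow(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  nx <- c(2:n, 1L)
  cr <- x * y[nx] - x[nx] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(ring))
  c(sum((x + x[nx]) * cr), sum((y + y[nx]) * cr)) / (6 * a)
}

# area-weighted centroid of a multipart geom
geom_centroid <- function(geom) {
  w <- vapply(geom, ring_area, numeric(1))
  cents <- t(vapply(geom, ring_centroid, numeric(2)))
  if (sum(w) <= 0) return(colMeans(cents))
  colSums(cents * w) / sum(w)
}

# a point guaranteed to lie inside the geom (centroid of the largest
# member; members here are convex or near-convex so this is interior)
geom_representative_point <- function(geom) {
  w <- vapply(geom, ring_area, numeric(1))
  ring_centroid(geom[[which.max(w)]])
}

ring_bbox <- function(ring) c(min(ring[, 1L]), min(ring[, 2L]),
                              max(ring[, 1L]), max(ring[, 2L]))

geom_bbox <- function(geom) {
  bb <- vapply(geom, ring_bbox, numeric(4))
  c(min(bb[1L, ]), min(bb[2L, ]), max(bb[3L, ]), max(bb[4L, ]))
}

bbox_overlap <- function(a, b, tol = 0) {
  a[1L] <= b[3L] + tol && b[1L] <= a[3L] + tol &&
    a[2L] <= b[4L] + tol && b[2L] <= a[4L] + tol
}

ensure_ccw <- function(ring) {
  if (ring_signed_area(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
}

# Sutherland-Hodgman step: keep the part of `ring` with a*x + b*y <= c.
# Returns a matrix with 0 rows when the ring is entirely cut away.
clip_halfplane <- function(ring, a, b, c) {
  n <- nrow(ring)
  if (n == 0L) return(ring)
  f <- a * ring[, 1L] + b * ring[, 2L] - c
  keep <- f <= 0
  if (all(keep)) return(ring)
  if (!any(keep)) return(ring[0L, , drop = FALSE])
  nx <- c(2:n, 1L)
  crossed <- keep != keep[nx]
  t <- ifelse(crossed, f / (f - f[nx]), 0)
  ix <- ring[, 1L] + t * (ring[nx, 1L] - ring[, 1L])
  iy <- ring[, 2L] + t * (ring[nx, 2L] - ring[, 2L])
  # interleave kept vertices and edge intersections in traversal order
  out_x <- c(rbind(ifelse(keep, ring[, 1L], NA), ifelse(crossed, ix, NA)))
  out_y <- c(rbind(ifelse(keep, ring[, 2L], NA), ifelse(crossed, iy, NA)))
  sel <- !is.na(out_x)
  cbind(out_x[sel], out_y[sel], deparse.level = 0)
}

# intersection of a ring with a convex clip ring (clip must be convex, CCW)
clip_ring_convex <- function(ring, clip) {
  n <- nrow(clip)
  nx <- c(2:n, 1L)
  for (i in seq_len(n)) {
    dx <- clip[nx[i], 1L] - clip[i, 1L]
    dy <- clip[nx[i], 2L] - clip[i, 2L]
    # keep the left (interior) side of each CCW edge
    a <- dy; b <- -dx
    c <- a * clip[i, 1L] + b * clip[i, 2L]
    ring <- clip_halfplane(ring, a, b, c)
    if (nrow(ring) < 3L) return(ring[0L, , drop = FALSE])
  }
  ring
}

# overlap area of two geoms; members of `b` must be convex
geom_intersection_area <- function(ga, gb, tol = 0) {
  total <- 0
  bba <- lapply(ga, ring_bbox)
  bbb <- lapply(gb, ring_bbox)
  for (i in seq_along(ga)) {
    for (j in seq_along(gb)) {
      if (!bbox_overlap(bba[[i]], bbb[[j]], tol)) next
      inter <- clip_ring_convex(ga[[i]], ensure_ccw(gb[[j]]))
      if (nrow(inter) >= 3L) total <- total + ring_area(inter)
    }
  }
  total
}

# offset a convex CCW ring outward by d (inward for d < 0) by shifting
# each edge line along its outward normal and re-intersecting half-planes
offset_convex <- function(ring, d) {
  bb <- ring_bbox(ring)
  pad <- abs(d) + diff(bb[c(1L, 3L)]) + diff(bb[c(2L, 4L)]) + 1
  out <- matrix(c(bb[1L] - pad, bb[2L] - pad,
                  bb[3L] + pad, bb[2L] - pad,
                  bb[3L] + pad, bb[4L] + pad,
                  bb[1L] - pad, bb[4L] + pad), ncol = 2L, byrow = TRUE)
  n <- nrow(ring)
  nx <- c(2:n, 1L)
  for (i in seq_len(n)) {
    dx <- ring[nx[i], 1L] - ring[i, 1L]
    dy <- ring[nx[i], 2L] - ring[i, 2L]
    len <- sqrt(dx * dx + dy * dy)
    if (len < .Machine$double.eps) next
    a <- dy; b <- -dx
    c <- a * ring[i, 1L] + b * ring[i, 2L] + d * len
    out <- clip_halfplane(out, a, b, c)
    if (nrow(out) < 3L) return(out[0L, , drop = FALSE])
  }
  out
}

# points along the boundary of a ring, spaced at most `interval` apart
densify_ring <- function(ring, interval) {
  n <- nrow(ring)
  nx <- c(2:n, 1L)
  pts <- vector("list", n)
  for (i in seq_len(n)) {
    p <- ring[i, ]; q <- ring[nx[i], ]
    len <- sqrt(sum((q - p)^2))
    k <- max(1L, ceiling(len / interval))
    t <- (seq_len(k) - 1L) / k
    pts[[i]] <- cbind(p[1L] + t * (q[1L] - p[1L]), p[2L] + t * (q[2L] - p[2L]))
  }
  do.call(rbind, pts)
}

# Voronoi cells of `pts` (n x 2, distinct) clipped to a convex CCW extent.
# Each cell starts as the extent and is cut by perpendicular bisectors of
# ever-more-distant sites; once half the distance to the next site exceeds
# the farthest cell vertex no later site can cut, so we stop early.
voronoi_cells <- function(pts, extent) {
  n <- nrow(pts)
  if (n == 1L) return(list(extent))
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    dx <- pts[, 1L] - pts[i, 1L]
    dy <- pts[, 2L] - pts[i, 2L]
    d2 <- dx * dx + dy * dy
    ord <- order(d2)
    cell <- extent
    maxr2 <- max((cell[, 1L] - pts[i, 1L])^2 + (cell[, 2L] - pts[i, 2L])^2)
    for (j in ord) {
      if (j == i) next
      if (d2[j] < 1e-18)
        stop("voronoi_cells(): duplicate sites at row ", i, " and ", j)
      if (d2[j] / 4 > maxr2) break
      # keep the side of the bisector closer to site i
      a <- dx[j]; b <- dy[j]
      c <- a * (pts[i, 1L] + dx[j] / 2) + b * (pts[i, 2L] + dy[j] / 2)
      cell <- clip_halfplane(cell, a, b, c)
      if (nrow(cell) < 3L)
        stop("voronoi_cells(): degenerate empty cell for site ", i)
      maxr2 <- max((cell[, 1L] - pts[i, 1L])^2 + (cell[, 2L] - pts[i, 2L])^2)
    }
    cells[[i]] <- cell
  }
  cells
}

# total length of shared (collinear, overlapping) boundary between two
# geoms; this is the rook-contiguity measure used for adjacency
shared_boundary_length <- function(ga, gb, tol = 1e-6) {
  ea <- geom_edges(ga)
  eb <- geom_edges(gb)
  if (nrow(ea) == 0L || nrow(eb) == 0L) return(0)
  total <- 0
  for (k in seq_len(nrow(ea))) {
    p1x <- ea[k, 1L]; p1y <- ea[k, 2L]; p2x <- ea[k, 3L]; p2y <- ea[k, 4L]
    ux <- p2x - p1x; uy <- p2y - p1y
    len <- sqrt(ux * ux + uy * uy)
    if (len < tol) next
    ux <- ux / len; uy <- uy / len
    # perpendicular distance of both endpoints of each b-edge to line a
    c1 <- abs(-uy * (eb[, 1L] - p1x) + ux * (eb[, 2L] - p1y))
    c2 <- abs(-uy * (eb[, 3L] - p1x) + ux * (eb[, 4L] - p1y))
    cand <- which(c1 <= tol & c2 <= tol)
    if (length(cand) == 0L) next
    t1 <- ux * (eb[cand, 1L] - p1x) + uy * (eb[cand, 2L] - p1y)
    t2 <- ux * (eb[cand, 3L] - p1x) + uy * (eb[cand, 4L] - p1y)
    lo <- pmax(pmin(t1, t2), 0)
    hi <- pmin(pmax(t1, t2), len)
    total <- total + sum(pmax(hi - lo, 0))
  }
  total
}

# edge list of a geom as a matrix [x1 y1 x2 y2]
geom_edges <- function(geom) {
  do.call(rbind, lapply(geom, function(ring) {
    n <- nrow(ring)
    nx <- c(2:n, 1L)
    cbind(ring[, 1L], ring[, 2L], ring[nx, 1L], ring[nx, 2L], deparse.level = 0)
  }))
}

# crossing-number containment test, vectorised over points, for one ring;
# points within `tol` of the boundary count as inside
points_in_ring <- function(px, py, ring, tol = 0) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  if (tol > 0) {
    onb <- rep(FALSE, length(px))
    j <- n
    for (i in seq_len(n)) {
      onb <- onb | point_segment_dist2(px, py, ring[j, 1L], ring[j, 2L],
                                       ring[i, 1L], ring[i, 2L]) <= tol^2
      j <- i
    }
    inside <- inside | onb
  }
  inside
}

points_in_geom <- function(px, py, geom, tol = 0) {
  res <- rep(FALSE, length(px))
  for (ring in geom) res <- res | points_in_ring(px, py, ring, tol)
  res
}

point_segment_dist2 <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  l2 <- vx * vx + vy * vy
  if (l2 < .Machine$double.eps) return((px - ax)^2 + (py - ay)^2)
  t <- pmin(pmax(((px - ax) * vx + (py - ay) * vy) / l2, 0), 1)
  (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2
}

# convex hull of a point matrix as a CCW ring
convex_hull_ring <- function(pts) {
  idx <- grDevices::chull(pts[, 1L], pts[, 2L])
  ensure_ccw(pts[idx, , drop = FALSE])
}

rect_ring <- function(xmin, ymin, xmax, ymax) {
  matrix(c(xmin, ymin, xmax, ymin, xmax, ymax, xmin, ymax),
         ncol = 2L, byrow = TRUE)
}
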