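#' Census-like tessellation of areal population units
#'
#' A `tessellation` is a planar partition of a study extent into areal
#' units, each carrying a population count. It is the central container of
#' the package: the synthetic landscape generator produces one, the
#' aggregation simulator coarsens one, and the disaggregation harness
#' spreads its counts onto a grid.
#'
#' Geometries live in a projected CRS with metre coordinates; unit areas
#' are stored in km\eqn{^2} and densities in persons/km\eqn{^2}
#' (recomputed from geometry, never trusted from input). A unit geometry is
#' a list of one or more counter-clockwise rings (n x 2 matrices) with
#' disjoint interiors; multipart units are legal and are flagged by
#' [validate_partition()].
#'
#' @param uid integer vector of unique unit identifiers.
#' @param pop non-negative integer population counts, one per unit.
#' @param geometry list of unit geometries; each element either a single
#'   ring matrix or a list of ring matrices.
#' @param crs character label of the projected CRS (default UTM zone 13N,
#'   the zone covering the Guadalajara study region this tool emulates).
#' @param extent bounding polygon (ring matrix); defaults to the bounding
#'   box of all geometries.
#' @param adjacency optional named list (by uid) of integer neighbour
#'   uids; built from geometry with [build_adjacency()] when `build_adj`
#'   is `TRUE` and `adjacency` is `NULL`.
#' @param build_adj logical; build rook adjacency now (can be costly for
#'   large inputs, so it is optional at construction).
#'
#' @return An object of class `tessellation`: a list with elements
#'   `units` (data.frame with columns `uid`, `pop`, `area`, `density`),
#'   `geometry`, `crs`, `extent`, `adjacency`.
#' @export
tessellation <- function(uid, pop, geometry, crs = "EPSG:32613",
                         extent = NULL, adjacency = NULL, build_adj = FALSE) {
  uid <- as.integer(uid)
  pop <- as.integer(round(pop))
  if (anyDuplicated(uid)) stop("tessellation(): duplicate uid")
  if (any(pop < 0)) stop("tessellation(): negative population count")
  if (length(uid) != length(pop) || length(uid) != length(geometry))
    stop("tessellation(): uid, pop and geometry lengths differ")
  geometry <- lapply(geometry, function(g) {
    if (is.matrix(g)) g <- list(g)
    lapply(g, ensure_ccw)
  })
  area_km2 <- vapply(geometry, geom_area, numeric(1)) / 1e6
  if (any(area_km2 <= 0)) stop("tessellation(): unit with non-positive area")
  if (is.null(extent)) {
    bb <- vapply(geometry, geom_bbox, numeric(4))
    extent <- rect_ring(min(bb[1L, ]), min(bb[2L, ]), max(bb[3L, ]), max(bb[4L, ]))
  }
  tess <- structure(list(
    units = data.frame(uid = uid, pop = pop, area = area_km2,
                       density = pop / area_km2),
    geometry = geometry,
    crs = crs,
    extent = ensure_ccw(extent),
    adjacency = adjacency
  ), class = "tessellation")
  if (is.null(adjacency) && build_adj)
    tess$adjacency <- build_adjacency(tess)
  tess
}

#' @export
print.tessellation <- function(x, ...) {
  cat(sprintf("<tessellation> %d units | total pop %s | total area %.3f km2 | ASR %.4f km\n",
              nrow(x$units), format(sum(x$units$pop), big.mark = ","),
              sum(x$units$area), sqrt(mean(x$units$area))))
  cat(sprintf("  CRS: %s | adjacency: %s\n", x$crs,
              if (is.null(x$adjacency)) "not built" else "built"))
  invisible(x)
}

n_units <- function(tess) nrow(tess$units)

tess_adj <- function(tess) {
  if (is.null(tess$adjacency)) stop("adjacency not built; call build_adjacency()")
  tess$adjacency
}

#' Is a CRS label projected?
#'
#' Geographic (longitude/latitude) systems are rejected by all area-based
#' operations: areas and densities are only meaningful in a projected CRS.
#' The check is label-based (EPSG:4326, WGS84, CRS84, longlat patterns).
#'
#' @param crs character CRS label.
#' @return logical.
#' @export
is_projected_crs <- function(crs) {
  !grepl("4326|longlat|lonlat|WGS ?84|CRS84", crs, ignore.case = TRUE)
}

stop_if_geographic <- function(crs) {
  if (!is_projected_crs(crs))
    stop("geographic (unprojected) CRS '", crs,
         "': areas require a projected CRS", call. = FALSE)
}

#' Rook contiguity from shared boundaries
#'
#' Two units are neighbours iff their boundaries share a collinear segment
#' of positive length (rook contiguity); point touches do not count. The
#' relation is symmetric and irreflexive. Candidate pairs are pre-filtered
#' by bounding-box overlap, then confirmed by measuring the shared
#' boundary length.
#'
#' @param tess a [tessellation()].
#' @param tol boundary tolerance in CRS units (metres): collinearity snap
#'   and the minimum shared length that counts as contiguity.
#' @return named list mapping each uid (as character) to an integer vector
#'   of neighbour uids (possibly empty: islands are legal).
#' @export
build_adjacency <- function(tess, tol = 1e-6) {
  n <- n_units(tess)
  uid <- tess$units$uid
  bb <- t(vapply(tess$geometry, geom_bbox, numeric(4)))
  adj <- stats::setNames(rep(list(integer(0)), n), as.character(uid))
  if (n < 2L) return(adj)
  for (i in seq_len(n - 1L)) {
    j_cand <- which(seq_len(n) > i &
                      bb[, 1L] <= bb[i, 3L] + tol & bb[i, 1L] <= bb[, 3L] + tol &
                      bb[, 2L] <= bb[i, 4L] + tol & bb[i, 2L] <= bb[, 4L] + tol)
    for (j in j_cand) {
      if (shared_boundary_length(tess$geometry[[i]], tess$geometry[[j]], tol) > tol) {
        adj[[i]] <- c(adj[[i]], uid[j])
        adj[[j]] <- c(adj[[j]], uid[i])
      }
    }
  }
  lapply(adj, sort)
}

#' Validate a tessellation as a planar partition
#'
#' Reports (never throws) on partition health: pairwise interior overlaps
#' beyond tolerance, islands (units with no rook neighbour), multipart
#' units, and coverage of the extent. Coverage is assessed by comparing
#' the summed unit area against the extent area (valid once overlaps are
#' below tolerance).
#'
#' @param tess a [tessellation()].
#' @param overlap_tol_km2 interior overlap area tolerated per unit pair
#'   (default 1e-6 km\eqn{^2}, i.e. 1 m\eqn{^2}).
#' @param sliver_frac tolerated uncovered fraction of the extent area
#'   (default 1e-4, i.e. 0.01\%).
#' @return A `partition_report`: list with `n_units`, `total_pop`,
#'   `total_area`, `n_overlaps`, `n_islands`, `n_multipart`,
#'   `covers_extent`.
#' @export
validate_partition <- function(tess, overlap_tol_km2 = 1e-6, sliver_frac = 1e-4) {
  n <- n_units(tess)
  bb <- t(vapply(tess$geometry, geom_bbox, numeric(4)))
  n_overlaps <- 0L
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      j_cand <- which(seq_len(n) > i &
                        bb[, 1L] < bb[i, 3L] & bb[i, 1L] < bb[, 3L] &
                        bb[, 2L] < bb[i, 4L] & bb[i, 2L] < bb[, 4L])
      for (j in j_cand) {
        ov <- geom_intersection_area(tess$geometry[[i]], tess$geometry[[j]])
        if (ov / 1e6 > overlap_tol_km2) n_overlaps <- n_overlaps + 1L
      }
    }
  }
  adj <- if (is.null(tess$adjacency)) build_adjacency(tess) else tess$adjacency
  n_islands <- sum(lengths(adj) == 0L)
  total_area <- sum(tess$units$area)
  extent_area <- ring_area(tess$extent) / 1e6
  structure(list(
    n_units = n,
    total_pop = sum(tess$units$pop),
    total_area = total_area,
    n_overlaps = n_overlaps,
    n_islands = as.integer(n_islands),
    n_multipart = sum(lengths(tess$geometry) > 1L),
    covers_extent = total_area >= extent_area * (1 - sliver_frac) - overlap_tol_km2
  ), class = "partition_report")
}

#' @export
print.partition_report <- function(x, ...) {
  cat(sprintf(paste0("<partition_report> %d units | pop %s | area %.3f km2 | ",
                     "%d overlaps | %d islands | %d multipart | covers extent: %s\n"),
              x$n_units, format(x$total_pop, big.mark = ","), x$total_area,
              x$n_overlaps, x$n_islands, x$n_multipart, x$covers_extent))
  invisible(x)
}

#' Fill street and open-space gaps by morphological tessellation
#'
#' Very high-resolution census units (blocks, even buildings) are commonly
#' digitised with streets and open space left as no-data corridors between
#' them. For aggregation work the units must instead share borders, as in
#' ordinary contiguous census geographies. This operation expands every
#' unit outward until it meets its neighbours, following a morphological
#' (Voronoi-based) tessellation: each source polygon boundary is shrunk
#' slightly inward, densified into seed points, and the Voronoi diagram of
#' all seed points over the extent is grouped back by source unit. Gaps
#' are absorbed into the nearest unit; unit count, uids and populations
#' are carried over unchanged; areas and densities are recomputed from the
#' new geometry.
#'
#' @param tess a [tessellation()] whose units may be separated by gaps.
#' @param extent optional bounding polygon; defaults to the convex hull of
#'   all input vertices buffered outward by one densification interval.
#' @param densify_interval spacing, in CRS units (metres), of the seed
#'   points placed along each boundary (default 10).
#' @param shrink inward offset, in CRS units, applied before densifying so
#'   that coincident borders of already-touching units produce distinct
#'   seed points (default `densify_interval / 10`). Assumes convex or
#'   near-convex member rings, which all package-generated units satisfy.
#' @return a new [tessellation()] that partitions the extent, with rook
#'   adjacency built.
#' @export
fill_gaps <- function(tess, extent = NULL, densify_interval = 10,
                      shrink = densify_interval / 10) {
  stop_if_geographic(tess$crs)
  n <- n_units(tess)
  # reject overlapping inputs, naming the first offending pair
  bb <- t(vapply(tess$geometry, geom_bbox, numeric(4)))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      j_cand <- which(seq_len(n) > i &
                        bb[, 1L] < bb[i, 3L] & bb[i, 1L] < bb[, 3L] &
                        bb[, 2L] < bb[i, 4L] & bb[i, 2L] < bb[, 4L])
      for (j in j_cand) {
        if (geom_intersection_area(tess$geometry[[i]], tess$geometry[[j]]) > 1) # > 1 m2
          stop(sprintf("fill_gaps(): input units %d and %d overlap",
                       tess$units$uid[i], tess$units$uid[j]))
      }
    }
  }
  all_pts <- do.call(rbind, lapply(tess$geometry, function(g) do.call(rbind, g)))
  if (is.null(extent)) {
    hull <- convex_hull_ring(all_pts)
    extent <- offset_convex(hull, densify_interval)
  }
  extent <- ensure_ccw(extent)
  if (!all(points_in_ring(all_pts[, 1L], all_pts[, 2L], extent, tol = 1e-6)))
    stop("fill_gaps(): extent does not contain all input geometries")

  seed_list <- vector("list", n)
  for (i in seq_len(n)) {
    pts_i <- lapply(tess$geometry[[i]], function(ring) {
      inner <- offset_convex(ring, -shrink)
      if (nrow(inner) < 3L) {
        # unit thinner than the shrink distance: seed from its centre
        matrix(ring_centroid(ring), ncol = 2L)
      } else {
        densify_ring(inner, densify_interval)
      }
    })
    seed_list[[i]] <- do.call(rbind, pts_i)
  }
  seeds <- do.call(rbind, seed_list)
  labels <- rep(seq_len(n), vapply(seed_list, nrow, integer(1)))
  dup <- duplicated(round(seeds, 9))
  seeds <- seeds[!dup, , drop = FALSE]
  labels <- labels[!dup]

  cells <- voronoi_cells(seeds, extent)
  geometry <- lapply(seq_len(n), function(i) cells[labels == i])

  out <- tessellation(tess$units$uid, tess$units$pop, geometry,
                      crs = tess$crs, extent = extent, build_adj = TRUE)
  # postcondition: each output unit still contains its source's
  # representative point
  for (i in seq_len(n)) {
    rp <- geom_representative_point(tess$geometry[[i]])
    if (!any(points_in_geom(rp[1L], rp[2L], out$geometry[[i]], tol = 1e-6)))
      warning("fill_gaps(): unit ", tess$units$uid[i],
              " no longer contains its source representative point")
  }
  out
}
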