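#' Reference grid specification
#'
#' An origin-anchored, axis-aligned square-pixel grid in a projected
#' CRS. `origin_x`/`origin_y` are the lower-left corner; rows are stored
#' top-down (row 1 is the northernmost), the usual raster convention.
#'
#' @param origin_x,origin_y lower-left corner, CRS units (metres).
#' @param res pixel size in metres (default 100, the people-per-pixel
#'   resolution this harness targets).
#' @param n_rows,n_cols grid dimensions.
#' @param crs projected CRS label.
#' @return a `grid_spec` object.
#' @export
grid_spec <- function(origin_x, origin_y, res = 100, n_rows, n_cols,
                      crs = "EPSG:32613") {
  if (res <= 0) stop("grid_spec(): pixel size must be > 0")
  if (n_rows < 1L || n_cols < 1L) stop("grid_spec(): dimensions must be >= 1")
  structure(list(origin_x = origin_x, origin_y = origin_y, res = res,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 crs = crs),
            class = "grid_spec")
}

#' A convenience grid covering a tessellation's extent
#'
#' @param tess a [tessellation()].
#' @param res pixel size in metres.
#' @return a [grid_spec()] whose pixels cover the extent bounding box.
#' @export
grid_for_tessellation <- function(tess, res = 100) {
  bb <- ring_bbox(tess$extent)
  grid_spec(bb[1L], bb[2L], res,
            n_rows = ceiling((bb[4L] - bb[2L]) / res),
            n_cols = ceiling((bb[3L] - bb[1L]) / res),
            crs = tess$crs)
}

# pixel centre coordinates; row 1 is the top row
grid_centers <- function(grid) {
  cx <- grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$res
  cy <- grid$origin_y + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * grid$res
  list(x = cx, y = cy)
}

#' People-per-pixel raster
#'
#' @param values numeric matrix (`n_rows` x `n_cols`, row 1 at the top);
#'   `NA` is nodata.
#' @param grid a [grid_spec()].
#' @param check_nonnegative require values >= 0 where not nodata
#'   (population rasters are counts; NDPI output reuses the container
#'   with the check off).
#' @return a `pop_raster` object.
#' @export
pop_raster <- function(values, grid, check_nonnegative = TRUE) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("pop_raster(): values do not match the grid dimensions")
  if (check_nonnegative && any(values < 0, na.rm = TRUE))
    stop("pop_raster(): negative values")
  structure(list(grid = grid, values = values), class = "pop_raster")
}

#' @export
print.pop_raster <- function(x, ...) {
  cat(sprintf("<pop_raster> %d x %d @ %g m | sum %.2f | %d nodata\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$res,
              sum(x$values, na.rm = TRUE), sum(is.na(x$values))))
  invisible(x)
}

#' Non-negative pixel weights for dasymetric redistribution
#'
#' The producer of the weights (e.g. a random-forest regression on
#' environmental covariates) is outside this package's scope; any
#' non-negative raster on the reference grid is accepted.
#'
#' @inheritParams pop_raster
#' @return a `weight_raster` object.
#' @export
weight_raster <- function(values, grid) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("weight_raster(): values do not match the grid dimensions")
  if (any(values < 0, na.rm = TRUE)) stop("weight_raster(): negative weights")
  structure(list(grid = grid, values = values), class = "weight_raster")
}

#' Assign grid pixels to areal units
#'
#' Each pixel belongs to the unit containing its centre point; pixels
#' whose centre falls in no unit are nodata. A centre lying exactly on a
#' shared edge is assigned to the lower uid (units are scanned in
#' ascending uid order and the first containing unit wins).
#'
#' @param tess a [tessellation()].
#' @param grid a [grid_spec()] in the same CRS.
#' @return integer matrix (`n_rows` x `n_cols`) of uids, `NA` outside
#'   all units.
#' @export
assign_pixels <- function(tess, grid) {
  if (!identical(tess$crs, grid$crs))
    stop("assign_pixels(): tessellation CRS '", tess$crs,
         "' does not match grid CRS '", grid$crs, "'")
  ctr <- grid_centers(grid)
  px <- rep(ctr$x, each = grid$n_rows)
  py <- rep(ctr$y, times = grid$n_cols)
  owner <- rep(NA_integer_, length(px))
  ord <- order(tess$units$uid)
  tol <- 1e-6
  for (i in ord) {
    bb <- geom_bbox(tess$geometry[[i]])
    cand <- which(is.na(owner) &
                    px >= bb[1L] - tol & px <= bb[3L] + tol &
                    py >= bb[2L] - tol & py <= bb[4L] + tol)
    if (length(cand) == 0L) next
    inside <- points_in_geom(px[cand], py[cand], tess$geometry[[i]], tol = tol)
    owner[cand[inside]] <- tess$units$uid[i]
  }
  matrix(owner, grid$n_rows, grid$n_cols)
}

#' Mass-preserving dasymetric redistribution
#'
#' Spreads each unit's population count over the pixels assigned to it,
#' proportionally to the weight raster (or in equal shares with
#' `weights = "uniform"`). Every unit's pixel values sum to its count
#' exactly, and the raster total equals the tessellation total: mass
#' preservation is the non-negotiable invariant. A unit whose weights
#' are all zero falls back to uniform shares; a unit with no assigned
#' pixel places its whole count on the pixel nearest its centroid.
#' Both situations are recorded in the run report attached to the
#' result.
#'
#' @param tess a [tessellation()].
#' @param grid a [grid_spec()].
#' @param weights a [weight_raster()] on `grid`, or `"uniform"`.
#' @param owner optional precomputed [assign_pixels()] matrix.
#' @return a [pop_raster()]; `attr(, "report")` lists
#'   `zero_weight_units` and `zero_pixel_units`.
#' @export
redistribute <- function(tess, grid, weights = "uniform", owner = NULL) {
  if (is.null(owner)) owner <- assign_pixels(tess, grid)
  if (identical(weights, "uniform")) {
    w <- matrix(1, grid$n_rows, grid$n_cols)
  } else {
    stopifnot(inherits(weights, "weight_raster"))
    if (!identical(unclass(weights$grid), unclass(grid)))
      stop("redistribute(): weights are not aligned to the grid")
    w <- weights$values
    w[is.na(w)] <- 0
  }
  out <- matrix(0, grid$n_rows, grid$n_cols)
  zero_weight_units <- integer(0)
  zero_pixel_units <- integer(0)
  ctr <- grid_centers(grid)
  ov <- as.vector(owner)
  idx_by_uid <- split(seq_along(ov), ov)
  for (i in seq_len(n_units(tess))) {
    uid <- tess$units$uid[i]
    popi <- tess$units$pop[i]
    pix <- idx_by_uid[[as.character(uid)]]
    if (is.null(pix) || length(pix) == 0L) {
      zero_pixel_units <- c(zero_pixel_units, uid)
      if (popi > 0) {
        cen <- geom_centroid(tess$geometry[[i]])
        col <- which.min(abs(ctr$x - cen[1L]))
        row <- which.min(abs(ctr$y - cen[2L]))
        out[row, col] <- out[row, col] + popi
      }
      next
    }
    wp <- w[pix]
    if (sum(wp) <= 0) {
      zero_weight_units <- c(zero_weight_units, uid)
      wp <- rep(1, length(pix))
    }
    out[pix] <- out[pix] + popi * wp / sum(wp)
  }
  out[is.na(owner) & out == 0] <- NA
  res <- pop_raster(out, grid)
  attr(res, "report") <- list(zero_weight_units = zero_weight_units,
                              zero_pixel_units = zero_pixel_units)
  res
}

#' Compare disaggregated realizations of a simulation archive
#'
#' Redistributes each requested (seed, level) realization onto a common
#' grid, then compares them: NDPI maps between the first two seeds at
#' every level, NDPI between the finest and coarsest level within each
#' seed, and bootstrap interval surfaces across seeds per level.
#'
#' @param archive a `sim_archive`.
#' @param grid a [grid_spec()].
#' @param weights a [weight_raster()] or `"uniform"`.
#' @param levels targets to include (default: all levels of the first
#'   run).
#' @param seeds seeds to include (default: all successful seeds).
#' @param alpha,n_boot,boot_seed passed to [bootstrap_interval()]
#'   (bootstrap skipped when fewer than 2 seeds).
#' @return list with `ppp` (`ppp[[seed]][[level]]` rasters),
#'   `ndpi_between_seeds` (per level, seed 1 vs seed 2),
#'   `ndpi_across_levels` (per seed, finest vs coarsest) and
#'   `bootstrap` (per level).
#' @export
compare_realizations <- function(archive, grid, weights = "uniform",
                                 levels = NULL, seeds = NULL,
                                 alpha = 0.05, n_boot = 200,
                                 boot_seed = NULL) {
  if (is.null(seeds)) seeds <- names(archive$runs)
  seeds <- as.character(seeds)
  if (is.null(levels)) levels <- archive$runs[[seeds[1L]]]$schedule
  if (length(seeds) * length(levels) < 2L)
    stop("compare_realizations(): need at least 2 (seed, level) realizations")
  owner <- assign_pixels(archive$base, grid)
  base_uid <- archive$base$units$uid
  ppp <- lapply(seeds, function(s) {
    run <- archive$runs[[s]]
    out <- lapply(levels, function(lv) {
      lev <- archive_level(archive, s, lv)
      # pixels keep their base-unit assignment; merged units own the
      # union of their members' pixels (membership via the merge log)
      map <- replay_merge_log(run$log, archive$base, target = lv)
      merged_owner <- matrix(map[as.character(owner)],
                             nrow(owner), ncol(owner))
      redistribute(lev$tess, grid, weights, owner = merged_owner)
    })
    names(out) <- as.character(levels)
    out
  })
  names(ppp) <- seeds
  ndpi_between <- NULL
  if (length(seeds) >= 2L) {
    ndpi_between <- lapply(as.character(levels), function(lv)
      ndpi(ppp[[1L]][[lv]], ppp[[2L]][[lv]]))
    names(ndpi_between) <- as.character(levels)
  }
  ndpi_across <- NULL
  if (length(levels) >= 2L) {
    fine <- as.character(max(levels))
    coarse <- as.character(min(levels))
    ndpi_across <- lapply(seeds, function(s)
      ndpi(ppp[[s]][[fine]], ppp[[s]][[coarse]]))
    names(ndpi_across) <- seeds
  }
  boots <- NULL
  if (length(seeds) >= 2L) {
    boots <- lapply(as.character(levels), function(lv)
      bootstrap_interval(lapply(seeds, function(s) ppp[[s]][[lv]]),
                         alpha = alpha, n_boot = n_boot, seed = boot_seed))
    names(boots) <- as.character(levels)
  }
  list(ppp = ppp, ndpi_between_seeds = ndpi_between,
       ndpi_across_levels = ndpi_across, bootstrap = boots)
}
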