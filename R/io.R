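#' Output file naming convention
#'
#' Simulated levels are named
#' `<prefix>_SIMULATED_Aggregation_seed_<seed>_scale_<scale>_target_<target>.<ext>`
#' so every file records the seed, the selection-curve scale factor and
#' the target unit count that produced it. [render_name()] and
#' [parse_name()] are exact inverses.
#'
#' @param seed integer simulation seed.
#' @param target integer target unit count.
#' @param scale selection-curve scale factor rho.
#' @param prefix name prefix (default `"SYN_admin"`).
#' @param ext file extension (default `"geojson"`).
#' @return an `output_name` object.
#' @export
output_name <- function(seed, target, scale = 4, prefix = "SYN_admin",
                        ext = "geojson") {
  structure(list(prefix = prefix, seed = as.integer(seed), scale = scale,
                 target = as.integer(target), ext = ext),
            class = "output_name")
}

#' @rdname output_name
#' @param name an `output_name`.
#' @export
render_name <- function(name) {
  stopifnot(inherits(name, "output_name"))
  sprintf("%s_SIMULATED_Aggregation_seed_%d_scale_%s_target_%d.%s",
          name$prefix, name$seed, format(name$scale, trim = TRUE),
          name$target, name$ext)
}

#' @rdname output_name
#' @param filename a file name produced by [render_name()].
#' @export
parse_name <- function(filename) {
  pat <- "^(.+)_SIMULATED_Aggregation_seed_([0-9]+)_scale_([0-9.]+)_target_([0-9]+)\\.([A-Za-z0-9]+)$"
  base <- basename(filename)
  if (!grepl(pat, base)) {
    seg <- if (!grepl("_SIMULATED_Aggregation_", base)) base
           else sub("^.*_SIMULATED_Aggregation_", "", base)
    stop("parse_name(): '", base,
         "' does not match the naming convention (offending segment: '",
         seg, "')")
  }
  m <- regmatches(base, regexec(pat, base))[[1L]]
  output_name(seed = as.integer(m[3L]), target = as.integer(m[5L]),
              scale = as.numeric(m[4L]), prefix = m[2L], ext = m[6L])
}

supported_vector_formats <- c("geojson")

check_format <- function(format) {
  if (!format %in% supported_vector_formats)
    stop("unsupported vector format '", format, "'; supported: ",
         paste(supported_vector_formats, collapse = ", "))
  format
}

# close rings and nest as GeoJSON MultiPolygon coordinates
geom_to_geojson_coords <- function(geom) {
  lapply(geom, function(ring) {
    closed <- rbind(ring, ring[1L, ])
    list(lapply(seq_len(nrow(closed)), function(i) closed[i, ]))
  })
}

#' Write one simulation level as a vector file
#'
#' The attribute table carries exactly the four canonical fields:
#' `P2010` (population count), `AREA` (km\eqn{^2}), `POP_DENS`
#' (persons/km\eqn{^2}; 0 for zero-population units, never NaN) and
#' `GUBID_INT` (unit id). Geometries are written as MultiPolygons in the
#' tessellation's CRS.
#'
#' @param tess a [tessellation()].
#' @param path output file path, or a directory when `name` is given.
#' @param name optional [output_name()]; when supplied the file name is
#'   rendered from it inside `path`.
#' @param format `"geojson"` (the supported vector format).
#' @return the written path, invisibly.
#' @export
write_level <- function(tess, path, name = NULL, format = "geojson") {
  check_format(format)
  if (!is.null(name)) path <- file.path(path, render_name(name))
  features <- lapply(seq_len(n_units(tess)), function(i) {
    u <- tess$units[i, ]
    list(type = "Feature",
         properties = list(P2010 = u$pop,
                           AREA = u$area,
                           POP_DENS = if (u$pop == 0) 0 else u$density,
                           GUBID_INT = u$uid),
         geometry = list(type = "MultiPolygon",
                         coordinates = geom_to_geojson_coords(tess$geometry[[i]])))
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name", properties = list(name = tess$crs)),
             features = features)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a simulation level written by [write_level()]
#'
#' @param path GeoJSON file path.
#' @param format `"geojson"`.
#' @param build_adj build rook adjacency after reading (default FALSE;
#'   costly for large files).
#' @return a [tessellation()].
#' @export
read_level <- function(path, format = "geojson", build_adj = FALSE) {
  check_format(format)
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  crs <- tryCatch(fc$crs$properties$name, error = function(e) NULL) %||% "unknown"
  uid <- integer(0); pop <- integer(0); geometry <- list()
  for (f in fc$features) {
    uid <- c(uid, as.integer(f$properties$GUBID_INT))
    pop <- c(pop, as.integer(f$properties$P2010))
    coords <- f$geometry$coordinates
    if (identical(f$geometry$type, "Polygon")) coords <- list(coords)
    geom <- lapply(coords, function(poly) {
      ring <- do.call(rbind, lapply(poly[[1L]], function(p)
        c(p[[1L]], p[[2L]])))
      ring[-nrow(ring), , drop = FALSE] # drop closing vertex
    })
    geometry <- c(geometry, list(geom))
  }
  tessellation(uid, pop, geometry, crs = crs, build_adj = build_adj)
}

#' Write / read a merge log as CSV
#'
#' Columns `seed`, `iteration`, `target`, `merged_uid`, `into_uid`, one
#' row per merge event in event order; the log is sufficient to replay
#' a simulation's entire zonal sequence (see [replay_merge_log()]).
#'
#' @param log a `merge_log` data.frame.
#' @param path CSV path.
#' @return `write_merge_log()` the path invisibly; `read_merge_log()` a
#'   `merge_log`.
#' @export
write_merge_log <- function(log, path) {
  cols <- c("seed", "iteration", "target", "merged_uid", "into_uid")
  stopifnot(all(cols %in% names(log)))
  utils::write.csv(log[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_merge_log
#' @export
read_merge_log <- function(path) {
  log <- utils::read.csv(path,
                         colClasses = c(seed = "integer", iteration = "integer",
                                        target = "integer",
                                        merged_uid = "integer",
                                        into_uid = "integer"))
  class(log) <- c("merge_log", "data.frame")
  log
}

#' Write a simulation archive to disk
#'
#' Mirrors the deposit layout: one `Units_<target>` folder per level
#' holding one vector file per seed (named by the [output_name()]
#' convention), plus a `Merge_Logs` folder with one CSV per seed.
#'
#' @param archive a `sim_archive`.
#' @param dir output directory (created if missing).
#' @param format vector format (see [write_level()]).
#' @param prefix file name prefix.
#' @return invisibly, the vector of written paths.
#' @export
write_archive <- function(archive, dir, format = "geojson",
                          prefix = "SYN_admin") {
  check_format(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log_dir <- file.path(dir, "Merge_Logs")
  dir.create(log_dir, showWarnings = FALSE)
  written <- character(0)
  rho <- archive$config$rho
  for (s in names(archive$runs)) {
    run <- archive$runs[[s]]
    for (tgt in names(run$levels)) {
      lvl_dir <- file.path(dir, paste0("Units_", tgt))
      dir.create(lvl_dir, showWarnings = FALSE)
      nm <- output_name(seed = run$seed, target = as.integer(tgt),
                        scale = rho, prefix = prefix, ext = format)
      written <- c(written,
                   write_level(run$levels[[tgt]]$tess, lvl_dir, name = nm,
                               format = format))
    }
    lp <- file.path(log_dir, sprintf("merge_log_seed_%s.csv", s))
    write_merge_log(run$log, lp)
    written <- c(written, lp)
  }
  invisible(written)
}

#' Write a unit-merge-frequency layer
#'
#' Attaches [unit_merge_frequency()] counts to the base geometry and
#' writes a choropleth-ready vector layer with fields `GUBID_INT` and
#' `FREQ`.
#'
#' @param base the base [tessellation()].
#' @param freq a data.frame from [unit_merge_frequency()].
#' @param path output GeoJSON path.
#' @return the path, invisibly.
#' @export
write_merge_frequency <- function(base, freq, path) {
  idx <- match(base$units$uid, freq$uid)
  features <- lapply(seq_len(n_units(base)), function(i) {
    list(type = "Feature",
         properties = list(GUBID_INT = base$units$uid[i],
                           FREQ = freq$count[idx[i]]),
         geometry = list(type = "MultiPolygon",
                         coordinates = geom_to_geojson_coords(base$geometry[[i]])))
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name", properties = list(name = base$crs)),
             features = features)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Write / read a raster as ESRI ASCII grid
#'
#' A plain-text single-band grid format (`ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value` header then rows top-down) readable
#' by standard GIS tooling. Implemented here because the package's
#' raster containers are plain matrices plus a [grid_spec()].
#'
#' @param raster a [pop_raster()] or [weight_raster()].
#' @param path output `.asc` path.
#' @param nodata nodata sentinel written for `NA` cells.
#' @return `write_asc()` the path invisibly; `read_asc()` a
#'   [pop_raster()].
#' @export
write_asc <- function(raster, path, nodata = -9999) {
  g <- raster$grid
  v <- raster$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", g$n_cols),
               paste("nrows", g$n_rows),
               paste("xllcorner", format(g$origin_x, scientific = FALSE)),
               paste("yllcorner", format(g$origin_y, scientific = FALSE)),
               paste("cellsize", format(g$res, scientific = FALSE)),
               paste("NODATA_value", nodata)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_asc
#' @param crs CRS label to attach on read (the ASCII grid format does
#'   not carry one).
#' @export
read_asc <- function(path, crs = "EPSG:32613") {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- stats::setNames(as.numeric(kv[, 2L]), tolower(kv[, 1L]))
  v <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(v) <- NULL
  v[v == vals[["nodata_value"]]] <- NA
  g <- grid_spec(vals[["xllcorner"]], vals[["yllcorner"]], vals[["cellsize"]],
                 n_rows = vals[["nrows"]], n_cols = vals[["ncols"]], crs = crs)
  pop_raster(v, g, check_nonnegative = FALSE)
}
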