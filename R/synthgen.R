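#' Specification of a synthetic census landscape
#'
#' Describes a square study area populated the way mixed urban/rural
#' census geographies look: a few dense urban cores tiled by many small
#' units, sparse rural surroundings tiled by few large ones, a share of
#' unpopulated units, and a heavy-tailed unit-area distribution with
#' area and density anticorrelated.
#'
#' Defaults describe a 30 km square with three urban cores and half a
#' million residents over 1,000 units; they are deliberately desk-scale
#' stand-ins for a metropolitan census extract, not a calibration to any
#' particular city.
#'
#' @param n_units number of areal units to generate (>= 2).
#' @param extent_km side length of the square study area, km.
#' @param n_cores number of urban cores (Gaussian clusters of unit seeds).
#' @param core_sd_km spatial spread (sd) of each core, km.
#' @param zero_pop_fraction fraction of units assigned population 0,
#'   taken from the largest-area units (in [0, 1)).
#' @param total_pop target total population; unit counts are integer and
#'   sum exactly to this value.
#' @param density_noise_sd sd of the multiplicative lognormal noise
#'   applied to the smooth density surface (on the log scale).
#' @param urban_fraction share of unit seed points drawn from the core
#'   mixture rather than the uniform rural background.
#' @param seed RNG seed; the whole landscape is a deterministic function
#'   of the spec including this seed.
#' @return an object of class `landscape_spec`.
#' @export
landscape_spec <- function(n_units = 1000, extent_km = 30, n_cores = 3,
                           core_sd_km = 2, zero_pop_fraction = 0.15,
                           total_pop = 500000, density_noise_sd = 0.7,
                           urban_fraction = 0.7, seed = 1L) {
  spec <- list(n_units = as.integer(n_units), extent_km = extent_km,
               n_cores = as.integer(n_cores), core_sd_km = core_sd_km,
               zero_pop_fraction = zero_pop_fraction,
               total_pop = as.integer(total_pop),
               density_noise_sd = density_noise_sd,
               urban_fraction = urban_fraction, seed = as.integer(seed))
  if (spec$n_units < 2L) stop("landscape_spec: n_units must be >= 2")
  if (spec$zero_pop_fraction < 0 || spec$zero_pop_fraction >= 1)
    stop("landscape_spec: zero_pop_fraction must be in [0, 1)")
  if (spec$total_pop < 0) stop("landscape_spec: total_pop must be >= 0")
  if (spec$extent_km <= 0) stop("landscape_spec: extent_km must be > 0")
  structure(spec, class = "landscape_spec")
}

#' @export
print.landscape_spec <- function(x, ...) {
  cat(sprintf(paste0("<landscape_spec> %d units | %.0f km extent | %d cores | ",
                     "pop %s | zero-pop %.0f%% | seed %d\n"),
              x$n_units, x$extent_km, x$n_cores,
              format(x$total_pop, big.mark = ","),
              100 * x$zero_pop_fraction, x$seed))
  invisible(x)
}

#' Generate a synthetic census landscape
#'
#' Draws unit seed points from a mixture of Gaussian urban cores and a
#' uniform rural background, takes their Voronoi tessellation over the
#' square extent, assigns populations from a smooth core-peaked density
#' surface times unit area times lognormal noise, zeroes out a quota of
#' the largest units, and rescales counts to the target total (largest
#' remainder rounding, so the total is met exactly).
#'
#' All randomness comes from one RNG stream keyed by `spec$seed` in a
#' fixed draw order (core centres, mixture components, coordinates,
#' noise), so the same spec always yields the identical tessellation;
#' the caller's RNG state is left untouched.
#'
#' @param spec a [landscape_spec()].
#' @param build_adj build rook adjacency on the result (default TRUE).
#' @return a [tessellation()] with `spec$n_units` units in a local
#'   projected CRS (metres), extent anchored at the origin.
#' @export
generate_landscape <- function(spec, build_adj = TRUE) {
  stopifnot(inherits(spec, "landscape_spec"))
  ext_m <- spec$extent_km * 1000
  n <- spec$n_units
  # require ~10 m mean seed spacing so the Voronoi construction stays
  # well-conditioned
  if (n > (ext_m / 10)^2)
    stop("generate_landscape(): extent too small to host ", n,
         " units at minimum spacing")
  extent <- rect_ring(0, 0, ext_m, ext_m)

  withr::with_seed(spec$seed, {
    cores <- cbind(stats::runif(spec$n_cores, 0.2 * ext_m, 0.8 * ext_m),
                   stats::runif(spec$n_cores, 0.2 * ext_m, 0.8 * ext_m))
    comp <- sample.int(spec$n_cores + 1L, n, replace = TRUE,
                       prob = c(1 - spec$urban_fraction,
                                rep(spec$urban_fraction / spec$n_cores,
                                    spec$n_cores)))
    pts <- matrix(NA_real_, n, 2L)
    rural <- comp == 1L
    pts[rural, ] <- cbind(stats::runif(sum(rural), 0, ext_m),
                          stats::runif(sum(rural), 0, ext_m))
    for (k in seq_len(spec$n_cores)) {
      sel <- which(comp == k + 1L)
      if (length(sel) == 0L) next
      pts[sel, ] <- cbind(
        stats::rnorm(length(sel), cores[k, 1L], spec$core_sd_km * 1000),
        stats::rnorm(length(sel), cores[k, 2L], spec$core_sd_km * 1000))
    }
    # redraw any point that fell outside the extent or collides with an
    # earlier point, from the uniform background
    repeat {
      bad <- pts[, 1L] <= 0 | pts[, 1L] >= ext_m |
        pts[, 2L] <= 0 | pts[, 2L] >= ext_m |
        duplicated(round(pts, 6))
      if (!any(bad)) break
      pts[bad, ] <- cbind(stats::runif(sum(bad), 0, ext_m),
                          stats::runif(sum(bad), 0, ext_m))
    }

    cells <- voronoi_cells(pts, extent)
    area_m2 <- vapply(cells, ring_area, numeric(1))
    cent <- t(vapply(cells, ring_centroid, numeric(2)))

    # smooth density surface: sum of core kernels plus a rural floor
    lambda <- rep(0.02, n)
    s2 <- (spec$core_sd_km * 1000)^2
    for (k in seq_len(spec$n_cores)) {
      d2 <- (cent[, 1L] - cores[k, 1L])^2 + (cent[, 2L] - cores[k, 2L])^2
      lambda <- lambda + exp(-d2 / (2 * s2))
    }
    noise <- exp(stats::rnorm(n, 0, spec$density_noise_sd))
    raw <- lambda * area_m2 * noise

    n_zero <- round(spec$zero_pop_fraction * n)
    zero_idx <- order(area_m2, decreasing = TRUE)[seq_len(n_zero)]
    raw[zero_idx] <- 0

    pop <- integer(n)
    pos <- which(raw > 0)
    if (length(pos) > 0L && spec$total_pop > 0L) {
      scaled <- raw[pos] * spec$total_pop / sum(raw[pos])
      base <- floor(scaled)
      rem <- spec$total_pop - sum(base)
      frac_order <- order(scaled - base, decreasing = TRUE)
      base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1
      pop[pos] <- as.integer(base)
    }
    tessellation(seq_len(n), pop, cells, crs = "LOCAL:metre",
                 extent = extent, build_adj = build_adj)
  })
}

#' Rank correlation between unit area and unit density
#'
#' Census geographies built to roughly equalise population per unit show
#' a strong negative association between unit area and population
#' density: small blocks tile the dense city, large polygons the sparse
#' countryside. This statistic (Spearman's rank correlation) checks that
#' a landscape, synthetic or real, carries that structure.
#'
#' @param tess a [tessellation()].
#' @return Spearman correlation in [-1, 1].
#' @export
area_density_correlation <- function(tess) {
  a <- tess$units$area
  d <- tess$units$density
  if (length(a) < 3L)
    stop("area_density_correlation(): need at least 3 units")
  if (length(unique(d)) < 2L || length(unique(a)) < 2L)
    stop("area_density_correlation(): correlation undefined for constant input")
  stats::cor(a, d, method = "spearman")
}

#' Write / read a landscape spec as a YAML config
#'
#' Flat key-value serialisation so a landscape is reproducible from a
#' text file checked into a study's repository.
#'
#' @param spec a [landscape_spec()].
#' @param path file path (conventionally `.yml`).
#' @return `read_landscape_spec()` returns a [landscape_spec()];
#'   `write_landscape_spec()` returns `path` invisibly.
#' @export
write_landscape_spec <- function(spec, path) {
  stopifnot(inherits(spec, "landscape_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_landscape_spec
#' @export
read_landscape_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(landscape_spec, vals)
}
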