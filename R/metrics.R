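#' Average spatial resolution
#'
#' The square root of the mean unit area: one length (km) summarising
#' how coarse an areal partition is, the standard single-number
#' resolution measure for population geographies.
#'
#' @param tess a [tessellation()].
#' @return ASR in km.
#' @export
asr <- function(tess) {
  if (n_units(tess) < 1L) stop("asr(): empty tessellation")
  sqrt(mean(tess$units$area))
}

#' Log-scale distribution summaries of a simulation level
#'
#' Pools the units of every seed at one level and summarises the
#' natural-log transformed unit areas, population counts and densities:
#' median, mean, and the 2.5th/97.5th percentiles. Zero-population units
#' have no finite log count or density and are excluded from those two
#' variables, with the exclusion count reported.
#'
#' @param archive a `sim_archive` from [run_simulations()].
#' @param level target unit count of the level to summarise.
#' @param variables which of `"area"`, `"pop"`, `"density"` to include.
#' @return data.frame with one row per variable: `level`, `variable`,
#'   `median`, `mean`, `p2.5`, `p97.5`, `n`, `n_excluded`.
#' @export
summarize_distributions <- function(archive, level,
                                    variables = c("area", "pop", "density")) {
  variables <- match.arg(variables, several.ok = TRUE)
  seeds <- names(archive$runs)
  if (length(seeds) == 0L) stop("summarize_distributions(): empty archive")
  pooled <- do.call(rbind, lapply(seeds, function(s)
    archive_level(archive, s, level)$tess$units))
  rows <- lapply(variables, function(v) {
    x <- pooled[[v]]
    n_excl <- 0L
    if (v %in% c("pop", "density")) {
      n_excl <- sum(x <= 0)
      x <- x[x > 0]
    }
    if (length(x) == 0L)
      stop("summarize_distributions(): all values zero for ", v)
    lx <- log(x)
    # inverse-ECDF (type 1) quantiles: pooling identical seeds is a no-op
    q <- stats::quantile(lx, c(0.025, 0.5, 0.975), names = FALSE, type = 1)
    data.frame(level = as.integer(level), variable = v,
               median = q[2L], mean = mean(lx), p2.5 = q[1L], p97.5 = q[3L],
               n = length(lx), n_excluded = n_excl)
  })
  do.call(rbind, rows)
}

#' How often each original unit was merged, across seeds
#'
#' For a given level, counts in how many seeds' simulations an original
#' unit was merged with at least one other unit by the time that level
#' was reached — i.e. its uid appears as `merged_uid` or `into_uid` in
#' the seed's cumulative log down to the level. Units merged in few
#' simulations give bootstrap-style summaries a small effective sample,
#' so this layer is the key metadata for deciding which units to trust.
#'
#' @param logs list of per-seed `merge_log`s (each one seed's full
#'   chain), or a `sim_archive`.
#' @param base the base [tessellation()].
#' @param level target unit count.
#' @return data.frame `uid`, `count` (0 <= count <= number of seeds),
#'   with attributes `level` and `n_seeds`; join on `uid` to the base
#'   geometry for choropleth export.
#' @export
unit_merge_frequency <- function(logs, base, level) {
  if (inherits(logs, "sim_archive"))
    logs <- lapply(logs$runs, function(r) r$log)
  counts <- stats::setNames(integer(nrow(base$units)),
                            as.character(base$units$uid))
  for (nm in names(logs) %||% seq_along(logs)) {
    log <- logs[[nm]]
    if (!any(log$target == level))
      stop("unit_merge_frequency(): level ", level,
           " absent from log of seed ", nm)
    ev <- log[log$target >= level, , drop = FALSE]
    touched <- unique(c(ev$merged_uid, ev$into_uid))
    counts[as.character(touched)] <- counts[as.character(touched)] + 1L
  }
  out <- data.frame(uid = base$units$uid, count = as.integer(counts))
  attr(out, "level") <- as.integer(level)
  attr(out, "n_seeds") <- length(logs)
  out
}

#' Normalised difference population index
#'
#' Per-pixel \eqn{(A - B)/(A + B)}: a bounded comparison of two
#' population rasters that weighs differences at low and high magnitudes
#' equally (the population analogue of NDVI). Pixels where both rasters
#' are zero map to 0 by convention (the two surfaces agree nobody lives
#' there); for non-negative inputs the result lies in [-1, 1].
#'
#' @param a,b [pop_raster()]s on the identical grid.
#' @return a raster of NDPI values on the same grid (class `pop_raster`
#'   container reused for convenience; values may be negative).
#' @export
ndpi <- function(a, b) {
  stopifnot(inherits(a, "pop_raster"), inherits(b, "pop_raster"))
  if (!identical(unclass(a$grid), unclass(b$grid)))
    stop("ndpi(): rasters are not on the same grid (alignment error)")
  s <- a$values + b$values
  v <- (a$values - b$values) / s
  v[!is.na(s) & s == 0] <- 0
  structure(list(grid = a$grid, values = v), class = "pop_raster")
}

#' Percentile bootstrap intervals across realizations
#'
#' Treats each realization (one seed's raster or per-unit table) as one
#' draw of the simulation, resamples realizations with replacement, and
#' returns the percentile interval of the per-cell bootstrap statistic
#' (the mean, by default). The per-cell effective sample size — how many
#' realizations actually inform a cell — is reported alongside, because
#' cells touched by few simulations yield intervals built from a small
#' effective sample.
#'
#' @param stack realizations: a list of [pop_raster()]s, a list of
#'   numeric vectors, or a matrix with one column per realization.
#' @param alpha interval miss probability (default 0.05: a 95\%
#'   interval).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed optional RNG seed for the resampling.
#' @param stat per-cell statistic (default `mean`), applied with NA
#'   values removed.
#' @return list with `lower`, `upper` (same shape as one realization),
#'   `n_eff`, `alpha`, `n_boot`.
#' @export
bootstrap_interval <- function(stack, alpha = 0.05, n_boot = 1000,
                               seed = NULL, stat = mean) {
  if (alpha <= 0 || alpha >= 1) stop("bootstrap_interval(): bad alpha")
  as_raster <- FALSE
  grid <- NULL
  if (is.list(stack) && length(stack) && inherits(stack[[1L]], "pop_raster")) {
    grid <- stack[[1L]]$grid
    dims <- dim(stack[[1L]]$values)
    as_raster <- TRUE
    stack <- vapply(stack, function(r) as.vector(r$values),
                    numeric(prod(dims)))
  } else if (is.list(stack)) {
    stack <- do.call(cbind, stack)
  }
  stack <- as.matrix(stack)
  R <- ncol(stack)
  if (R < 2L) stop("bootstrap_interval(): need at least 2 realizations")
  n_eff <- rowSums(!is.na(stack))
  mean_fast <- identical(stat, mean) || identical(stat, base::mean)
  boot_fun <- function() {
    idx <- sample.int(R, R, replace = TRUE)
    if (mean_fast) rowMeans(stack[, idx, drop = FALSE], na.rm = TRUE)
    else apply(stack[, idx, drop = FALSE], 1L, stat, na.rm = TRUE)
  }
  run <- function() {
    bs <- matrix(NA_real_, nrow(stack), n_boot)
    for (b in seq_len(n_boot)) bs[, b] <- boot_fun()
    lo <- apply(bs, 1L, stats::quantile, probs = alpha / 2, na.rm = TRUE,
                names = FALSE)
    hi <- apply(bs, 1L, stats::quantile, probs = 1 - alpha / 2, na.rm = TRUE,
                names = FALSE)
    list(lo = lo, hi = hi)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  shape <- function(v) {
    if (as_raster)
      structure(list(grid = grid,
                     values = matrix(v, grid$n_rows, grid$n_cols)),
                class = "pop_raster")
    else v
  }
  list(lower = shape(res$lo), upper = shape(res$hi),
       n_eff = if (as_raster) matrix(n_eff, grid$n_rows, grid$n_cols) else n_eff,
       alpha = alpha, n_boot = n_boot)
}
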