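#' Configuration for the aggregation simulator
#'
#' @param rho positive shape parameter of the area-based selection curve
#'   (default 4: a balanced mix of small dense and larger sparse units
#'   gets selected for merging).
#' @param seeds integer RNG seeds, one simulation trajectory per seed
#'   (default 100 seeds).
#' @param schedule optional strictly decreasing integer vector of target
#'   unit counts; when `NULL`, [default_schedule()] of the input size is
#'   used at run time.
#' @param tie_break partner tie-break rule; only `"lowest-uid"` is
#'   implemented (deterministic per seed).
#' @param island_policy what to do with units that have no neighbour:
#'   `"exclude-from-selection"` gives them selection probability 0 and
#'   errors only if the target becomes unreachable.
#' @param criterion merge-partner criterion: `"density-similarity"`
#'   (the neighbour with the most similar population density — the
#'   density-preserving rule this simulator exists for) or
#'   `"random-neighbour"` (ablation variant that picks a neighbour
#'   uniformly at random).
#' @return an `aggregation_config` object.
#' @export
aggregation_config <- function(rho = 4, seeds = 1:100, schedule = NULL,
                               tie_break = "lowest-uid",
                               island_policy = "exclude-from-selection",
                               criterion = "density-similarity") {
  if (rho <= 0) stop("aggregation_config: rho must be > 0")
  tie_break <- match.arg(tie_break, "lowest-uid")
  island_policy <- match.arg(island_policy, "exclude-from-selection")
  criterion <- match.arg(criterion, c("density-similarity", "random-neighbour"))
  if (!is.null(schedule)) {
    schedule <- as.integer(schedule)
    if (any(schedule < 1L)) stop("aggregation_config: targets must be >= 1")
    if (length(schedule) > 1L && any(diff(schedule) >= 0L))
      stop("aggregation_config: schedule must be strictly decreasing")
  }
  structure(list(rho = rho, seeds = as.integer(seeds), schedule = schedule,
                 tie_break = tie_break, island_policy = island_policy,
                 criterion = criterion),
            class = "aggregation_config")
}

#' Default coarsening schedule
#'
#' Target unit counts at 95%, 90%, ..., down to `lowest_fraction` of the
#' base unit count, in `step_fraction` steps, each rounded half-up. On a
#' 55,146-unit base this yields 18 levels from 52,389 down to 5,515 in
#' 2,757-unit (5\%) increments.
#'
#' @param n base number of units.
#' @param step_fraction fraction of `n` between consecutive levels
#'   (default 0.05).
#' @param lowest_fraction coarsest level as a fraction of `n`
#'   (default 0.10).
#' @return strictly decreasing integer vector of targets.
#' @export
default_schedule <- function(n, step_fraction = 0.05, lowest_fraction = 0.10) {
  if (step_fraction <= 0 || lowest_fraction <= 0 ||
      lowest_fraction >= 1 - step_fraction)
    stop("default_schedule(): need 0 < lowest_fraction < 1 - step_fraction")
  fracs <- round(seq(1 - step_fraction, lowest_fraction, by = -step_fraction), 10)
  targets <- as.integer(floor(fracs * n + 0.5)) # round half up
  if (any(targets < 1L) || (length(targets) > 1L && any(diff(targets) >= 0L)))
    stop("default_schedule(): n = ", n,
         " is too small for distinct targets at these fractions")
  targets
}

# normalised selection weights from raw areas:
# z_i = (a_i - min a) / (max a - min a), w_i = 1 / (1 + z_i^rho)
weights_from_areas <- function(areas, rho) {
  rng <- range(areas)
  if (rng[2L] - rng[1L] <= 0) return(rep(1 / length(areas), length(areas)))
  z <- (areas - rng[1L]) / (rng[2L] - rng[1L])
  w <- 1 / (1 + z^rho)
  w / sum(w)
}

#' Quasi-random selection weights over unit areas
#'
#' The probability that unit \eqn{i} is selected for dissolution follows
#' a decreasing curve over the min-max normalised unit area
#' \eqn{z_i}: \eqn{w_i = 1/(1 + z_i^\rho)}, normalised to sum to one.
#' Small units are preferred; with \eqn{\rho = 4} the smallest unit is
#' twice as likely as the largest, with the curve flat near the small end
#' so the bulk of small urban units share similar probability. Equal
#' areas degrade gracefully to the uniform distribution.
#'
#' @param tess a [tessellation()] with at least 2 units.
#' @param rho positive shape parameter.
#' @return a `selection_weights` object: list with `uids` and `probs`
#'   (probabilities sum to 1 and are non-increasing in area).
#' @export
selection_weights <- function(tess, rho = 4) {
  if (n_units(tess) < 2L) stop("selection_weights(): need at least 2 units")
  if (any(tess$units$area <= 0)) stop("selection_weights(): non-positive area")
  if (rho <= 0) stop("selection_weights(): rho must be > 0")
  structure(list(uids = tess$units$uid,
                 probs = weights_from_areas(tess$units$area, rho),
                 rho = rho),
            class = "selection_weights")
}

#' Draw one unit according to selection weights
#'
#' @param weights a [selection_weights()] object.
#' @param selectable optional uids eligible for selection (islands are
#'   excluded by the caller under the island policy); probabilities are
#'   renormalised over this set.
#' @return the selected uid; advances the R RNG stream.
#' @export
sample_unit <- function(weights, selectable = NULL) {
  uids <- weights$uids
  probs <- weights$probs
  if (!is.null(selectable)) {
    keep <- uids %in% selectable
    uids <- uids[keep]
    probs <- probs[keep]
  }
  if (length(uids) == 0L || sum(probs) <= 0)
    stop("sample_unit(): no selectable unit (island exhaustion)")
  uids[sample.int(length(uids), 1L, prob = probs)]
}

#' Most density-similar neighbour
#'
#' The merge partner of a selected unit is the rook neighbour whose
#' population density is closest (minimum absolute difference); ties are
#' broken by the lowest uid so a seed's trajectory is deterministic.
#'
#' @param tess a [tessellation()] with adjacency built.
#' @param uid the selected unit.
#' @return the partner uid.
#' @export
choose_merge_partner <- function(tess, uid) {
  adj <- tess_adj(tess)
  nb <- adj[[as.character(uid)]]
  if (is.null(nb) || length(nb) == 0L)
    stop("choose_merge_partner(): unit ", uid, " has no neighbours (island)")
  d0 <- tess$units$density[match(uid, tess$units$uid)]
  dn <- tess$units$density[match(nb, tess$units$uid)]
  delta <- abs(dn - d0)
  cand <- nb[delta == min(delta)]
  min(cand)
}

#' Dissolve one unit into an adjacent one
#'
#' The combined unit keeps `into_uid`, its geometry is the union of the
#' two (kept as the multipart collection of the members, whose interiors
#' are disjoint), its population is the sum, and area/density are
#' recomputed. Its neighbours are the union of the pair's neighbours
#' minus the pair itself; every other unit is untouched.
#'
#' @param tess a [tessellation()] with adjacency built.
#' @param merged_uid uid of the unit being dissolved (disappears).
#' @param into_uid uid of the adjacent unit that absorbs it.
#' @return a new [tessellation()] with one unit fewer.
#' @export
merge_units <- function(tess, merged_uid, into_uid) {
  st <- state_from_tess(tess)
  st <- state_merge(st, merged_uid, into_uid)
  state_to_tess(st, tess)
}

# --- internal mutable-ish state used by the run loop -----------------
# plain list of parallel vectors; uids index the adjacency list by name

state_from_tess <- function(tess) {
  adj <- tess_adj(tess)
  list(uid = tess$units$uid,
       pop = as.numeric(tess$units$pop),
       area = tess$units$area,
       geom = tess$geometry,
       adj = adj)
}

state_to_tess <- function(st, base) {
  tess <- structure(list(
    units = data.frame(uid = st$uid, pop = as.integer(st$pop),
                       area = st$area, density = st$pop / st$area),
    geometry = st$geom,
    crs = base$crs,
    extent = base$extent,
    adjacency = st$adj
  ), class = "tessellation")
  tess
}

state_merge <- function(st, merged_uid, into_uid) {
  im <- match(merged_uid, st$uid)
  ii <- match(into_uid, st$uid)
  if (is.na(im) || is.na(ii)) stop("merge_units(): unknown uid")
  if (merged_uid == into_uid) stop("merge_units(): cannot merge a unit with itself")
  km <- as.character(merged_uid); ki <- as.character(into_uid)
  if (!(into_uid %in% st$adj[[km]]))
    stop("merge_units(): units ", merged_uid, " and ", into_uid,
         " are not adjacent (contiguity violation)")
  st$pop[ii] <- st$pop[ii] + st$pop[im]
  st$area[ii] <- st$area[ii] + st$area[im]
  st$geom[[ii]] <- c(st$geom[[ii]], st$geom[[im]])
  new_nb <- sort(setdiff(union(st$adj[[km]], st$adj[[ki]]),
                         c(merged_uid, into_uid)))
  for (nb in new_nb) {
    kn <- as.character(nb)
    v <- st$adj[[kn]]
    v <- v[v != merged_uid]
    if (!(into_uid %in% v)) v <- sort(c(v, into_uid))
    st$adj[[kn]] <- v
  }
  st$adj[[ki]] <- new_nb
  st$adj[[km]] <- NULL
  st$uid <- st$uid[-im]
  st$pop <- st$pop[-im]
  st$area <- st$area[-im]
  st$geom <- st$geom[-im]
  st
}

# one level's worth of merging; does NOT seed the RNG (the caller owns
# the stream), records `seed_label` in the log
run_level <- function(st, target, rho, criterion, seed_label) {
  seed_label <- as.integer(seed_label)
  n_start <- length(st$uid)
  n_events <- n_start - target
  ev_merged <- integer(n_events)
  ev_into <- integer(n_events)
  for (it in seq_len(n_events)) {
    islands <- lengths(st$adj[as.character(st$uid)]) == 0L
    probs <- weights_from_areas(st$area, rho)
    probs[islands] <- 0
    if (sum(probs) <= 0)
      stop("island exhaustion: no selectable unit among uids ",
           paste(st$uid, collapse = ", "))
    probs <- probs / sum(probs)
    sel <- st$uid[sample.int(length(st$uid), 1L, prob = probs)]
    nb <- st$adj[[as.character(sel)]]
    if (criterion == "density-similarity") {
      d0 <- st$pop[match(sel, st$uid)] / st$area[match(sel, st$uid)]
      dn <- st$pop[match(nb, st$uid)] / st$area[match(nb, st$uid)]
      delta <- abs(dn - d0)
      partner <- min(nb[delta == min(delta)])
    } else {
      partner <- nb[sample.int(length(nb), 1L)]
    }
    st <- state_merge(st, sel, partner)
    ev_merged[it] <- sel
    ev_into[it] <- partner
  }
  log <- data.frame(seed = rep(seed_label, n_events),
                    iteration = seq_len(n_events),
                    target = rep(as.integer(target), n_events),
                    merged_uid = ev_merged,
                    into_uid = ev_into)
  class(log) <- c("merge_log", "data.frame")
  list(state = st, log = log)
}

empty_merge_log <- function() {
  log <- data.frame(seed = integer(0), iteration = integer(0),
                    target = integer(0), merged_uid = integer(0),
                    into_uid = integer(0))
  class(log) <- c("merge_log", "data.frame")
  log
}

#' Coarsen a tessellation to a target unit count
#'
#' Repeats the select-and-dissolve iteration until exactly `target`
#' units remain: selection weights are recomputed from the current unit
#' areas at every iteration, a unit is drawn quasi-randomly (small units
#' preferred), and it is dissolved into its most density-similar rook
#' neighbour. Population is conserved exactly; every merge is logged.
#'
#' @param tess a [tessellation()] with adjacency built.
#' @param target desired number of units (<= current count).
#' @param cfg an [aggregation_config()].
#' @param seed optional integer; when given, the R RNG is seeded before
#'   the run (when `NULL` the current RNG stream continues, which is how
#'   chained schedules share one stream per seed).
#' @param seed_label value recorded in the log's `seed` column (defaults
#'   to `seed`, or NA when the stream is being continued anonymously).
#' @return list with elements `tess` (the coarsened [tessellation()])
#'   and `log` (a `merge_log` data.frame with columns `seed`,
#'   `iteration`, `target`, `merged_uid`, `into_uid`).
#' @export
run_to_target <- function(tess, target, cfg = aggregation_config(),
                          seed = NULL, seed_label = seed) {
  target <- as.integer(target)
  if (target > n_units(tess))
    stop("run_to_target(): target ", target, " exceeds current ",
         n_units(tess), " units")
  if (!is.null(seed)) set.seed(seed)
  seed_label <- if (is.null(seed_label)) NA_integer_ else as.integer(seed_label)
  if (target == n_units(tess))
    return(list(tess = tess, log = empty_merge_log()))
  res <- run_level(state_from_tess(tess), target, cfg$rho, cfg$criterion,
                   seed_label)
  list(tess = state_to_tess(res$state, tess), log = res$log)
}

#' Run one seed's full coarsening chain
#'
#' Levels are produced in descending order and chained: each level's
#' input is the previous level's output, under one continuous RNG stream
#' seeded once per trajectory. Per-level iteration counters restart at 1.
#'
#' @param tess the base [tessellation()] with adjacency built.
#' @param cfg an [aggregation_config()]; a `NULL` schedule means
#'   [default_schedule()] of the base size.
#' @param seed integer seed of this trajectory.
#' @return a `sim_run`: list with `seed`, `levels` (named by target:
#'   each a list `tess`, `log`) and `log` (all events concatenated in
#'   chain order).
#' @export
run_schedule <- function(tess, cfg = aggregation_config(), seed = 1L) {
  schedule <- if (is.null(cfg$schedule)) default_schedule(n_units(tess))
              else cfg$schedule
  if (schedule[1L] > n_units(tess))
    stop("run_schedule(): first target exceeds base unit count")
  set.seed(seed)
  st <- state_from_tess(tess)
  levels <- vector("list", length(schedule))
  names(levels) <- as.character(schedule)
  logs <- vector("list", length(schedule))
  for (k in seq_along(schedule)) {
    res <- run_level(st, schedule[k], cfg$rho, cfg$criterion, seed)
    st <- res$state
    levels[[k]] <- list(tess = state_to_tess(st, tess), log = res$log)
    logs[[k]] <- res$log
  }
  full <- do.call(rbind, logs)
  class(full) <- c("merge_log", "data.frame")
  structure(list(seed = as.integer(seed), schedule = schedule,
                 levels = levels, log = full),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("<sim_run> seed %d | %d levels (%s ... %s) | %d merges\n",
              x$seed, length(x$schedule), x$schedule[1L],
              x$schedule[length(x$schedule)], nrow(x$log)))
  invisible(x)
}

#' Run the full simulation archive across seeds
#'
#' Executes [run_schedule()] independently for every seed in the config
#' (each seed re-seeds its own stream, so results do not depend on the
#' order seeds are run in). One seed's failure is recorded in the run
#' report without aborting the others. When `out_dir` is given, every
#' level is written via [write_archive()].
#'
#' @param tess the base [tessellation()] with adjacency built.
#' @param cfg an [aggregation_config()].
#' @param out_dir optional directory to write level files and merge logs.
#' @param format vector format for written levels (see [write_level()]).
#' @param quiet suppress per-seed progress messages.
#' @return a `sim_archive`: list with `base`, `config`, `runs` (named by
#'   seed), and `report` (data.frame seed/ok/error).
#' @export
run_simulations <- function(tess, cfg = aggregation_config(), out_dir = NULL,
                            format = "geojson", quiet = TRUE) {
  runs <- list()
  report <- data.frame(seed = cfg$seeds, ok = FALSE, error = NA_character_)
  for (i in seq_along(cfg$seeds)) {
    s <- cfg$seeds[i]
    if (!quiet) message(format(Sys.time(), "%H:%M:%S"), " seed ", s, " ...")
    res <- tryCatch(run_schedule(tess, cfg, s), error = function(e) e)
    if (inherits(res, "error")) {
      report$error[i] <- conditionMessage(res)
    } else {
      runs[[as.character(s)]] <- res
      report$ok[i] <- TRUE
    }
  }
  archive <- structure(list(base = tess, config = cfg, runs = runs,
                            report = report),
                       class = "sim_archive")
  if (!is.null(out_dir)) write_archive(archive, out_dir, format = format)
  archive
}

#' @export
print.sim_archive <- function(x, ...) {
  cat(sprintf("<sim_archive> %d/%d seeds ok | %d levels | base %d units\n",
              sum(x$report$ok), nrow(x$report),
              length(x$runs[[1L]]$schedule %||% integer(0)),
              n_units(x$base)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# level lookup helper shared by the metrics functions
archive_level <- function(archive, seed, target) {
  run <- archive$runs[[as.character(seed)]]
  if (is.null(run)) stop("seed ", seed, " not in archive")
  lev <- run$levels[[as.character(target)]]
  if (is.null(lev)) stop("level ", target, " not in archive for seed ", seed)
  lev
}

#' Replay a merge log on the base tessellation
#'
#' Reconstructs, from the log alone (no RNG, no weights), which original
#' unit ended up in which coarsened unit at a given level: every event
#' relabels all originals currently mapped to `merged_uid` as
#' `into_uid`. Events belonging to levels at or above `target` (targets
#' descend along a chain) are applied in order.
#'
#' @param log a `merge_log` (one seed's chain).
#' @param base the base [tessellation()] the log was produced from.
#' @param target level to reconstruct; default applies the whole log.
#' @return named integer vector: for each base uid (names), the uid of
#'   the coarsened unit containing it.
#' @export
replay_merge_log <- function(log, base, target = NULL) {
  map <- stats::setNames(base$units$uid, base$units$uid)
  ev <- if (is.null(target)) log else log[log$target >= target, , drop = FALSE]
  for (r in seq_len(nrow(ev))) {
    map[map == ev$merged_uid[r]] <- ev$into_uid[r]
  }
  map
}
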