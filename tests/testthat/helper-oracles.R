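# independent oracles, deliberately implemented differently from the
# package internals they cross-check

# brute-force O(n^2) rook contiguity: two units are neighbours iff some
# edge of one has at least two distinct sampled interior points lying on
# the other's boundary (sampling instead of segment algebra)
oracle_adjacency <- function(tess, n_samples = 33, tol = 1e-7) {
  n <- nrow(tess$units)
  uid <- tess$units$uid
  on_boundary <- function(px, py, geom) {
    for (ring in geom) {
      m <- nrow(ring)
      j <- m
      for (i in seq_len(m)) {
        ax <- ring[j, 1L]; ay <- ring[j, 2L]
        bx <- ring[i, 1L]; by <- ring[i, 2L]
        vx <- bx - ax; vy <- by - ay
        l2 <- vx^2 + vy^2
        if (l2 > 0) {
          t <- ((px - ax) * vx + (py - ay) * vy) / l2
          t <- pmin(pmax(t, 0), 1)
          d2 <- (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2
          if (d2 <= tol^2) return(TRUE)
        }
        j <- i
      }
    }
    FALSE
  }
  adj <- stats::setNames(rep(list(integer(0)), n), as.character(uid))
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      hits <- 0L
      for (ring in tess$geometry[[a]]) {
        m <- nrow(ring)
        j <- m
        for (i in seq_len(m)) {
          ts <- seq(0.02, 0.98, length.out = n_samples)
          px <- ring[j, 1L] + ts * (ring[i, 1L] - ring[j, 1L])
          py <- ring[j, 2L] + ts * (ring[i, 2L] - ring[j, 2L])
          for (k in seq_along(ts)) {
            if (on_boundary(px[k], py[k], tess$geometry[[b]])) hits <- hits + 1L
            if (hits >= 2L) break
          }
          if (hits >= 2L) break
          j <- i
        }
        if (hits >= 2L) break
      }
      if (hits >= 2L) {
        adj[[a]] <- c(adj[[a]], uid[b])
        adj[[b]] <- c(adj[[b]], uid[a])
      }
    }
  }
  lapply(adj, sort)
}

# direct longhand evaluation of the selection-probability curve,
# written as an explicit per-element loop
oracle_selection_probs <- function(areas, rho) {
  n <- length(areas)
  amin <- min(areas); amax <- max(areas)
  w <- numeric(n)
  for (i in seq_len(n)) {
    if (amax == amin) {
      w[i] <- 1
    } else {
      z <- (areas[i] - amin) / (amax - amin)
      w[i] <- 1 / (1 + z^rho)
    }
  }
  w / sum(w)
}

# check that a replayed membership map reproduces a level: same unit id
# set, and per merged unit the base pops/areas/member-ring counts add up
expect_replay_matches_level <- function(map, base, level_tess, tol = 1e-9) {
  groups <- split(as.integer(names(map)), map)
  expect_setequal(as.integer(names(groups)), level_tess$units$uid)
  for (gid in names(groups)) {
    members <- match(groups[[gid]], base$units$uid)
    row <- match(as.integer(gid), level_tess$units$uid)
    expect_identical(sum(base$units$pop[members]),
                     level_tess$units$pop[row])
    expect_lt(abs(sum(base$units$area[members]) -
                    level_tess$units$area[row]),
              tol * max(level_tess$units$area[row], 1))
    expect_identical(sum(lengths(base$geometry[members])),
                     length(level_tess$geometry[[row]]))
  }
}
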