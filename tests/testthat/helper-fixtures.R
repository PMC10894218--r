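# fixtures are built in code; geometries use metre coordinates

square_ring <- function(x0, y0, side) {
  matrix(c(x0, y0, x0 + side, y0, x0 + side, y0 + side, x0, y0 + side),
         ncol = 2L, byrow = TRUE)
}

# nx x ny grid of square cells, uids row-major from the bottom-left
grid_tess <- function(nx, ny, side = 100, pops = NULL, build_adj = TRUE) {
  n <- nx * ny
  if (is.null(pops)) pops <- seq_len(n)
  geoms <- vector("list", n)
  k <- 1L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      geoms[[k]] <- square_ring((i - 1L) * side, (j - 1L) * side, side)
      k <- k + 1L
    }
  }
  tessellation(seq_len(n), pops, geoms, crs = "LOCAL:metre",
               build_adj = build_adj)
}

# rectangles with chosen areas (km2) and populations, laid side by side
# and sharing vertical edges; handy when exact areas/densities are needed
strip_tess <- function(areas_km2, pops, build_adj = TRUE) {
  height <- 1000 # 1 km tall
  widths <- areas_km2 * 1e6 / height
  x0 <- c(0, cumsum(widths))
  geoms <- lapply(seq_along(widths), function(i)
    matrix(c(x0[i], 0, x0[i + 1L], 0, x0[i + 1L], height, x0[i], height),
           ncol = 2L, byrow = TRUE))
  tessellation(seq_along(widths), pops, geoms, crs = "LOCAL:metre",
               build_adj = build_adj)
}

# small landscapes are reused across files; cache per (n, seed)
.fixture_cache <- new.env(parent = emptyenv())

cached_landscape <- function(n_units = 300, seed = 42, ...) {
  key <- paste0("L", n_units, "_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_landscape(
      landscape_spec(n_units = n_units, seed = seed, ...))
  .fixture_cache[[key]]
}
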