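test_that("pixels are assigned by centre containment with lower-uid ties", {
  one <- tessellation(7L, 100L, list(square_ring(0, 0, 400)),
                      crs = "LOCAL:metre", build_adj = TRUE)
  g <- grid_spec(0, 0, res = 100, n_rows = 4, n_cols = 4, crs = "LOCAL:metre")
  owner <- assign_pixels(one, g)
  expect_true(all(owner == 7L))

  # 2-unit vertical split of a 4x4 grid -> 8 pixels each
  split2 <- tessellation(1:2, c(10, 20),
                         list(matrix(c(0, 0, 200, 0, 200, 400, 0, 400),
                                     ncol = 2, byrow = TRUE),
                              matrix(c(200, 0, 400, 0, 400, 400, 200, 400),
                                     ncol = 2, byrow = TRUE)),
                         crs = "LOCAL:metre", build_adj = TRUE)
  owner2 <- assign_pixels(split2, g)
  expect_identical(sum(owner2 == 1L), 8L)
  expect_identical(sum(owner2 == 2L), 8L)

  # centre exactly on the shared edge -> lower uid
  g1 <- grid_spec(150, 150, res = 100, n_rows = 1, n_cols = 1,
                  crs = "LOCAL:metre") # centre at (200, 200), on the split
  expect_identical(as.integer(assign_pixels(split2, g1)), 1L)

  gwrong <- grid_spec(0, 0, res = 100, n_rows = 4, n_cols = 4, crs = "EPSG:32613")
  expect_error(assign_pixels(split2, gwrong), "CRS")
})

test_that("redistribution preserves mass under uniform and custom weights", {
  unit4 <- tessellation(1L, 100L, list(square_ring(0, 0, 200)),
                        crs = "LOCAL:metre", build_adj = TRUE)
  g <- grid_spec(0, 0, res = 100, n_rows = 2, n_cols = 2, crs = "LOCAL:metre")
  r <- redistribute(unit4, g)
  expect_true(all(r$values == 25))

  # weights {3,1} over a 2-pixel unit of pop 8 -> pixels {6,2}
  two <- tessellation(1L, 8L, list(square_ring(0, 0, 200)),
                      crs = "LOCAL:metre", build_adj = TRUE)
  g2 <- grid_spec(0, 0, res = 100, n_rows = 1, n_cols = 2, crs = "LOCAL:metre")
  w <- weight_raster(matrix(c(3, 1), 1, 2), g2)
  r2 <- redistribute(two, g2, w)
  expect_equal(as.vector(r2$values), c(6, 2))

  # global conservation on a synthetic landscape, within 1e-9 relative
  tess <- cached_landscape(n_units = 60, seed = 9)
  grid <- grid_for_tessellation(tess, res = 1000)
  set.seed(3)
  wr <- weight_raster(matrix(runif(grid$n_rows * grid$n_cols),
                             grid$n_rows, grid$n_cols), grid)
  for (weights in list("uniform", wr)) {
    ras <- redistribute(tess, grid, weights)
    expect_lt(abs(sum(ras$values, na.rm = TRUE) - sum(tess$units$pop)) /
                sum(tess$units$pop), 1e-9)
  }
})

test_that("per-unit pixel sums equal the unit counts", {
  set.seed(23)
  tess <- grid_tess(4, 4, side = 1000, pops = sample.int(500, 16))
  grid <- grid_spec(0, 0, res = 250, n_rows = 16, n_cols = 16,
                    crs = "LOCAL:metre")
  wr <- weight_raster(matrix(runif(256), 16, 16), grid)
  owner <- assign_pixels(tess, grid)
  for (weights in list("uniform", wr)) {
    ras <- redistribute(tess, grid, weights, owner = owner)
    expect_length(attr(ras, "report")$zero_pixel_units, 0L)
    sums <- tapply(as.vector(ras$values), as.vector(owner), sum)
    expect_equal(as.vector(sums[as.character(tess$units$uid)]),
                 as.numeric(tess$units$pop), tolerance = 1e-9)
  }
})

test_that("zero-weight and zero-pixel units fall back without losing mass", {
  # unit 2 is too small to contain any 100 m pixel centre
  tiny <- tessellation(1:2, c(90L, 10L),
                       list(matrix(c(0, 0, 195, 0, 195, 200, 0, 200),
                                   ncol = 2, byrow = TRUE),
                            matrix(c(195, 0, 200, 0, 200, 200, 195, 200),
                                   ncol = 2, byrow = TRUE)),
                       crs = "LOCAL:metre", build_adj = TRUE)
  g <- grid_spec(0, 0, res = 100, n_rows = 2, n_cols = 2, crs = "LOCAL:metre")
  r <- redistribute(tiny, g)
  rep <- attr(r, "report")
  expect_identical(rep$zero_pixel_units, 2L)
  expect_equal(sum(r$values, na.rm = TRUE), 100)

  wzero <- weight_raster(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE), g)
  one <- tessellation(1L, 40L, list(square_ring(0, 0, 200)),
                      crs = "LOCAL:metre", build_adj = TRUE)
  # all-zero weights within the unit in the top row -> uniform fallback
  gtop <- grid_spec(0, 100, res = 100, n_rows = 1, n_cols = 2,
                    crs = "LOCAL:metre")
  wz <- weight_raster(matrix(0, 1, 2), gtop)
  rz <- redistribute(one, gtop, wz)
  expect_identical(attr(rz, "report")$zero_weight_units, 1L)
  expect_equal(as.vector(rz$values), c(20, 20))
})

test_that("block-summed fine redistribution equals coarse redistribution", {
  # unit boundary aligned to the coarse 200 m grid
  split2 <- tessellation(1:2, c(120L, 60L),
                         list(matrix(c(0, 0, 200, 0, 200, 400, 0, 400),
                                     ncol = 2, byrow = TRUE),
                              matrix(c(200, 0, 400, 0, 400, 400, 200, 400),
                                     ncol = 2, byrow = TRUE)),
                         crs = "LOCAL:metre", build_adj = TRUE)
  fine <- grid_spec(0, 0, res = 100, n_rows = 4, n_cols = 4, crs = "LOCAL:metre")
  coarse <- grid_spec(0, 0, res = 200, n_rows = 2, n_cols = 2, crs = "LOCAL:metre")
  set.seed(8)
  wfine <- matrix(runif(16), 4, 4)
  wcoarse <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    wcoarse[i, j] <- sum(wfine[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  rf <- redistribute(split2, fine, weight_raster(wfine, fine))
  rc <- redistribute(split2, coarse, weight_raster(wcoarse, coarse))
  block <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    block[i, j] <- sum(rf$values[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(block, rc$values, tolerance = 1e-9)
})

test_that("realization comparison: self-NDPI is zero, divergence grows with coarseness", {
  tess <- cached_landscape(n_units = 200, seed = 31)
  arc <- run_simulations(tess, aggregation_config(seeds = 1:2,
                                                  schedule = c(190, 40)))
  grid <- grid_for_tessellation(tess, res = 1500)
  cmp <- compare_realizations(arc, grid, levels = c(190, 40), n_boot = 30,
                              boot_seed = 1)
  # same realization against itself
  self_nd <- ndpi(cmp$ppp[["1"]][["40"]], cmp$ppp[["1"]][["40"]])
  expect_true(all(self_nd$values == 0, na.rm = TRUE))
  # between-seed divergence larger at the coarse level
  expect_gt(mean(abs(cmp$ndpi_between_seeds[["40"]]$values), na.rm = TRUE),
            mean(abs(cmp$ndpi_between_seeds[["190"]]$values), na.rm = TRUE))
  # within-seed fine-vs-coarse differences concentrate in large source units
  nd <- cmp$ndpi_across_levels[["1"]]
  owner <- assign_pixels(tess, grid)
  a_px <- tess$units$area[match(as.vector(owner), tess$units$uid)]
  v <- abs(as.vector(nd$values))
  ok <- !is.na(v) & !is.na(a_px)
  hot <- v[ok] >= stats::quantile(v[ok], 0.9)
  expect_gt(mean(a_px[ok][hot]), mean(a_px[ok]))
  # bootstrap surfaces exist per level with the seed count as sample
  expect_true(all(cmp$bootstrap[["40"]]$n_eff <= 2))
})
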