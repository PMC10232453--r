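# GeoTIFF round trips, background masking, temporal aggregation, and
# nearest-neighbor resampling.

test_that("grid_spec validates its fields and compares with tolerance", {
  expect_error(grid_spec(0, 4), "dimensions")
  expect_error(grid_spec(2, 2, pixel_size_x = 0), "nonzero")
  g <- grid_spec(4, 4, origin_x = -180, origin_y = 70,
                 pixel_size_x = 0.5, pixel_size_y = -0.5)
  g2 <- grid_spec(4, 4, origin_x = -180 + 1e-12, origin_y = 70,
                  pixel_size_x = 0.5, pixel_size_y = -0.5)
  g3 <- grid_spec(4, 4, origin_x = -179, origin_y = 70,
                  pixel_size_x = 0.5, pixel_size_y = -0.5)
  expect_true(grid_equal(g, g2))
  expect_false(grid_equal(g, g3))
  ctr <- grid_centers(g)
  expect_equal(ctr$x, c(-179.75, -179.25, -178.75, -178.25))
  expect_equal(ctr$y[1], 69.75)
})

test_that("read_cube masks the background value and rejects mismatched grids", {
  td <- withr::local_tempdir()
  g <- grid_spec(2, 2)
  write_geotiff(file.path(td, "a.tif"), matrix(c(30, 50, -9999, 70), 2, 2), g)
  cube <- read_cube(file.path(td, "a.tif"), 1981L)
  expect_equal(cube$valid[1, , ], matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2))
  expect_true(is.na(cube$values[1, 1, 2]))

  # no cell equals the background -> all valid
  write_geotiff(file.path(td, "b.tif"), matrix(1:4, 2, 2), g)
  expect_true(all(read_cube(file.path(td, "b.tif"), 1981L)$valid))

  # a file on a different grid is refused, naming the offender
  write_geotiff(file.path(td, "c.tif"), matrix(1:6, 2, 3), grid_spec(2, 3))
  expect_error(read_cube(file.path(td, c("a.tif", "c.tif")), c(1981L, 1982L)),
               "c\\.tif")
  expect_error(read_cube(file.path(td, "nope.tif"), 1981L), "no such file")
})

test_that("write_cube follows the VHIopt_year naming and six-decimal round trip", {
  td <- withr::local_tempdir()
  set.seed(3)
  cube <- rand_cube(2, 3, 4, seed = 3)
  cube$valid[1, 2, 2] <- FALSE
  cube$values[2, 1, 1] <- 12.3456789
  paths <- write_cube(cube, td)
  expect_equal(basename(paths), c("VHIopt_1981.tif", "VHIopt_1982.tif"))
  back <- read_cube(paths, cube$times)
  expect_identical(back$valid, cube$valid)
  expect_equal(back$values[2, 1, 1], 12.345679)
  expect_equal(back$values[back$valid],
               round(cube$values, 6)[cube$valid], tolerance = 1e-12)
  expect_true(grid_equal(back$grid, cube$grid))
})

test_that("an external TIFF implementation reads our files identically", {
  td <- withr::local_tempdir()
  g <- grid_spec(3, 4, origin_x = -10, origin_y = 20,
                 pixel_size_x = 0.25, pixel_size_y = -0.25, crs_id = "EPSG:4326")
  m <- matrix(seq(0.1234567, by = 1.1, length.out = 12), 3, 4)
  path <- file.path(td, "x.tif")
  write_geotiff(path, m, g)
  script <- paste(
    "import sys, tifffile, numpy as np",
    "tf = tifffile.TiffFile(sys.argv[1])",
    "a = tf.asarray()",
    "tags = tf.pages[0].tags",
    "print(a.shape[0], a.shape[1], a.dtype, round(float(a.sum()), 6))",
    "print(*tags['ModelPixelScaleTag'].value[:2])",
    "print(*tags['ModelTiepointTag'].value[3:5])",
    sep = "; ")
  out <- system2("python", c("-c", shQuote(script), path), stdout = TRUE)
  expect_equal(out[1], paste("3 4 float64", round(sum(m), 6)))
  expect_equal(scan(text = out[2], quiet = TRUE), c(0.25, 0.25))
  expect_equal(scan(text = out[3], quiet = TRUE), c(-10, 20))
})

test_that("weekly data aggregate to annual and monthly arithmetic means", {
  # 52 weeks of one year, values 1..52 -> annual mean 26.5
  wk <- data.frame(year = 1990L, week = 1:52)
  cube <- raster_cube(array(1:52, c(52, 1, 1)), wk, grid_spec(1, 1))
  ann <- aggregate_time(cube, "annual")
  expect_equal(ann$values[1, 1, 1], 26.5)
  expect_equal(ann$times$year, 1990L)

  # one month with values (40, invalid, 60) -> mean 50
  wk3 <- data.frame(year = 1990L, week = 1:3)
  c3 <- raster_cube(array(c(40, NA, 60), c(3, 1, 1)), wk3, grid_spec(1, 1))
  mon <- aggregate_time(c3, "monthly")
  expect_equal(mon$times$month, 1L)
  expect_equal(mon$values[1, 1, 1], 50)

  # all weeks invalid -> invalid annual cell
  call_na <- raster_cube(array(NA_real_, c(3, 1, 1)), wk3, grid_spec(1, 1))
  expect_false(aggregate_time(call_na, "annual")$valid[1, 1, 1])

  # min_count above the available count also invalidates
  expect_false(aggregate_time(c3, "annual", min_count = 3L)$valid[1, 1, 1])

  expect_error(aggregate_time(ann, "annual"), "already annual")
  expect_error(aggregate_time(raster_cube(array(1, c(1, 1, 1)),
                                          data.frame(year = 1L, month = 1L),
                                          grid_spec(1, 1)), "monthly"),
               "weekly")
})

test_that("annual mean over all valid weeks equals the direct computation", {
  set.seed(9)
  wk <- data.frame(year = rep(1990:1991, each = 52), week = rep(1:52, 2))
  v <- array(rnorm(104 * 4, 50, 10), c(104, 2, 2))
  v[sample(length(v), 40)] <- NA
  cube <- raster_cube(v, wk, grid_spec(2, 2))
  ann <- aggregate_time(cube, "annual")
  for (yi in 1:2) for (r in 1:2) for (cc in 1:2) {
    ref <- mean(v[wk$year == 1989 + yi, r, cc], na.rm = TRUE)
    expect_equal(ann$values[yi, r, cc], ref)
  }
})

test_that("nearest-neighbor resampling replicates blocks, is idempotent, and keeps validity", {
  src <- layers_cube(list(matrix(c(1, 3, 2, 4), 2, 2)))     # [[1,2],[3,4]]
  fine <- grid_spec(4, 4, origin_x = 0, origin_y = 2,
                    pixel_size_x = 0.5, pixel_size_y = -0.5)
  # match the source grid placement
  src$grid <- grid_spec(2, 2, origin_x = 0, origin_y = 2)
  out <- resample_nearest(src, fine)
  expect_equal(out$values[1, , ],
               matrix(c(1, 1, 3, 3, 1, 1, 3, 3, 2, 2, 4, 4, 2, 2, 4, 4), 4, 4))

  # identity on the source's own grid
  same <- resample_nearest(src, src$grid)
  expect_equal(same$values, src$values)
  expect_identical(same$valid, src$valid)

  # idempotence on the output grid
  again <- resample_nearest(out, fine)
  expect_equal(again$values, out$values)

  # invalid source cell -> all mapped target cells invalid
  src$valid[1, 1, 1] <- FALSE
  out2 <- resample_nearest(src, fine)
  expect_false(any(out2$valid[1, 1:2, 1:2]))
  expect_true(all(out2$valid[1, 3:4, ]))

  # CRS mismatch is refused
  expect_error(resample_nearest(src, grid_spec(4, 4, crs_id = "EPSG:3857")),
               "CRS mismatch")
})

test_that("equidistant resampling ties go to the smaller source index", {
  # target center exactly between the two source centers at 0.5 and 1.5
  src <- layers_cube(list(matrix(c(10, 20), 1, 2)),
                     grid = grid_spec(1, 2, origin_x = 0, origin_y = 1))
  tgt <- grid_spec(1, 1, origin_x = 0.5, origin_y = 1, pixel_size_x = 1)
  expect_equal(resample_nearest(src, tgt)$values[1, 1, 1], 10)
})

test_that("altering values under the mask never changes downstream results", {
  cube <- rand_cube(10, 3, 3, seed = 5)
  cube$valid[3, 2, 2] <- FALSE
  tampered <- cube
  tampered$values[3, 2, 2] <- 1e6
  expect_equal(compute_vhi(cube, cube)$values[cube$valid],
               compute_vhi(tampered, tampered)$values[tampered$valid])
  p1 <- correlation_profile(pixel_series(cube, 2, 2), pixel_series(cube, 2, 2),
                            pixel_series(cube, 2, 2), min_overlap = 3L)
  p2 <- correlation_profile(pixel_series(tampered, 2, 2),
                            pixel_series(tampered, 2, 2),
                            pixel_series(tampered, 2, 2), min_overlap = 3L)
  expect_identical(p1, p2)
})
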