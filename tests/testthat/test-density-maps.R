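test_that("MRC write/read round-trips at float32 precision", {
  set.seed(2)
  m <- density_map(array(stats::runif(3 * 4 * 5), c(3, 4, 5)), 1.5, c(2, 3, 4))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m, f)
  rt <- read_mrc(f)
  expect_identical(dim(rt$values), dim(m$values))
  expect_equal(rt$spacing, m$spacing)
  expect_equal(rt$origin, m$origin)
  expect_lt(max(abs(rt$values - m$values)), 1e-6)  # float32 rounding only
  # a second round trip is bit-exact (values already float32)
  f2 <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(rt, f2)
  expect_identical(read_mrc(f2)$values, rt$values)
  ones <- density_map(array(1, c(2, 2, 2)), 1)
  f3 <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(ones, f3)
  expect_equal(sum(read_mrc(f3)$values), 8)
})

test_that("MRC origin precedence: ORIGIN record wins, else nstart * spacing", {
  m <- density_map(array(as.numeric(1:8), c(2, 2, 2)), 2, c(5, 5, 5))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m, f)
  expect_equal(read_mrc(f)$origin, c(5, 5, 5))
  # craft a header with ORIGIN = 0 and nstart = (1, 2, 3)
  raw <- readBin(f, "raw", file.info(f)$size)
  raw[197:208] <- writeBin(numeric(3), raw(), size = 4, endian = "little")
  raw[17:28] <- writeBin(1:3, raw(), size = 4, endian = "little")
  f2 <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw, f2)
  expect_equal(read_mrc(f2)$origin, c(2, 4, 6))   # nstart * spacing
})

test_that("Situs ASCII maps round-trip and validate value counts", {
  f <- withr::local_tempfile(fileext = ".situs")
  writeLines(c("2.0 0 0 0 2 2 2", "1 2 3 4 5", "6 7 8"), f)
  m <- read_situs(f)
  expect_identical(dim(m$values), c(2L, 2L, 2L))
  expect_equal(m$spacing, 2)
  expect_equal(as.vector(m$values), as.numeric(1:8))
  # 7 values under a 2x2x2 header
  f2 <- withr::local_tempfile(fileext = ".situs")
  writeLines(c("2.0 0 0 0 2 2 2", "1 2 3 4 5 6 7"), f2)
  expect_error(read_situs(f2), "does not match")
  # MRC -> Situs -> MRC preserves values to ASCII precision
  set.seed(5)
  big <- density_map(array(stats::runif(27), c(3, 3, 3)), 1, c(-1, 0, 1))
  fm <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(big, fm)
  a <- read_mrc(fm)
  fs <- withr::local_tempfile(fileext = ".situs")
  write_situs(a, fs)
  b <- read_situs(fs)
  expect_lt(max(abs(b$values - a$values)) / max(abs(a$values)), 1e-5)
  expect_equal(b$origin, a$origin)
})

test_that("map simulation conserves atom weight and is symmetric and linear", {
  tpl <- density_map(array(0, c(31, 31, 31)), 1, c(0, 0, 0))
  cfg <- simulation_config(resolution = 4)  # sigma = 2
  m1 <- ca_model(matrix(c(15, 15, 15), 1, 3))
  s1 <- simulate_map(m1, tpl, cfg)
  expect_equal(sum(s1$values), 1, tolerance = 1e-3)
  # atom on a lattice point: reflection symmetry about it
  expect_equal(s1$values, s1$values[31:1, , ], tolerance = 1e-14)
  expect_equal(s1$values, s1$values[, , 31:1], tolerance = 1e-14)
  # off-lattice atom still deposits its full weight
  m_off <- ca_model(matrix(c(15.3, 14.6, 15.9), 1, 3))
  expect_equal(sum(simulate_map(m_off, tpl, cfg)$values), 1, tolerance = 1e-3)
  # linearity: two atoms = sum of the single-atom maps
  m2 <- ca_model(matrix(c(12, 15, 15), 1, 3))
  m12 <- ca_model(rbind(c(15, 15, 15), c(12, 15, 15)))
  s2 <- simulate_map(m2, tpl, cfg)
  s12 <- simulate_map(m12, tpl, cfg)
  expect_equal(s12$values, s1$values + s2$values, tolerance = 1e-12)
  # weights scale deposits
  m1w <- m1
  m1w$atoms$weight <- 2.5
  expect_equal(sum(simulate_map(m1w, tpl, cfg)$values), 2.5, tolerance = 2.5e-3)
  # aliasing guard
  expect_error(simulate_map(m1, tpl, simulation_config(resolution = 0.5)),
               "alias")
})

test_that("zero padding preserves values, sums and world coordinates", {
  set.seed(7)
  m <- density_map(array(stats::runif(8), c(2, 2, 2)), 1.2, c(3, 3, 3))
  expect_identical(zero_pad(m, 0), m)
  p <- zero_pad(m, 10)
  expect_identical(dim(p$values), c(22L, 22L, 22L))
  expect_equal(sum(p$values), sum(m$values))
  # the world coordinate of the original first voxel is unchanged
  expect_equal(p$origin + 10 * p$spacing, m$origin)
  expect_equal(p$values[11:12, 11:12, 11:12], m$values)
  expect_error(zero_pad(m, -1), "non-negative")
})

test_that("zone masking zeroes distant voxels and crops to minimal bounds", {
  u <- density_map(array(1, c(31, 31, 31)), 1, c(0, 0, 0))
  atom <- ca_model(matrix(c(15, 15, 15), 1, 3))
  mk <- mask_zone(u, atom, radius = 5)
  idx <- which(mk$values > 0, arr.ind = TRUE)
  centers <- sweep((idx - 1) * mk$spacing, 2, mk$origin, `+`)
  d <- sqrt(rowSums(sweep(centers, 2, c(15, 15, 15))^2))
  expect_true(all(d <= 5 + 1e-12))
  expect_true(all(mk$values <= u$values))
  expect_lte(sum(mk$values), sum(u$values))
  # minimal-bounds crop of the unit-spacing single-atom case is 11^3
  mkc <- mask_zone(u, atom, radius = 5, minimal_bounds = TRUE)
  expect_identical(dim(mkc$values), c(11L, 11L, 11L))
  expect_equal(mkc$origin, c(10, 10, 10))
  # radius beyond the grid diagonal leaves the map unchanged
  mk_inf <- mask_zone(u, atom, radius = 100)
  expect_equal(mk_inf$values, u$values)
  # masking everything is an error
  far <- ca_model(matrix(c(500, 500, 500), 1, 3))
  expect_error(mask_zone(u, far, radius = 5), "no voxel")
})
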