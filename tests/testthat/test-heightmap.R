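test_that("heightmap constructor enforces its invariants", {
  expect_error(heightmap(matrix(c(1, NA, 2, 3), 2), 1), "finite")
  expect_error(heightmap(matrix(1, 2, 2), -1), "positive")
  expect_error(heightmap(matrix(numeric(0), 0, 0), 1), "at least one pixel")
  hm <- heightmap(matrix(1:6, 2, 3), c(2, 3))
  expect_equal(dim(hm), c(2L, 3L))
  expect_equal(hm$pixel_size_x, 2)
  expect_equal(hm$pixel_size_y, 3)
})

test_that("rms roughness matches its definition and invariances", {
  expect_equal(rms_roughness(heightmap(matrix(5, 4, 4), 10)), 0)
  alt <- heightmap(matrix(c(3, -3), 8, 8), 1)   # alternating +h/-h
  expect_equal(rms_roughness(alt), 3)
  set.seed(11)
  g <- matrix(rnorm(1024^2, 50, 5), 1024)
  hm <- heightmap(g, 2.44)
  direct <- sqrt(mean((g - mean(g))^2))         # brute-force formula
  expect_equal(rms_roughness(hm), direct)
  expect_equal(rms_roughness(hm), 5, tolerance = 0.05 / 5)
  # translation and transposition invariance
  expect_equal(rms_roughness(heightmap(g + 123.4, 2.44)), rms_roughness(hm))
  expect_equal(rms_roughness(heightmap(t(g), 2.44)), rms_roughness(hm))
})

test_that("scan kinematics reproduce instrument conventions", {
  g <- scan_geometry(1024, 2500, 0.2, retrace_included = TRUE)
  k <- scan_kinematics(g)
  expect_equal(k$total_sliding_distance_nm, 5.12e6)   # ~5.1 mm
  expect_equal(k$sliding_velocity_nm_s, 500)          # 0.5 um/s, one-way
  expect_equal(scan_kinematics(scan_geometry(0, 2500, 0.2))$total_sliding_distance_nm, 0)
  # linear in lines and width
  k2 <- scan_kinematics(scan_geometry(2048, 1250, 0.2))
  expect_equal(k2$total_sliding_distance_nm, k$total_sliding_distance_nm)
  expect_error(scan_geometry(-1, 1, 1), "non-negative")
})

test_that("GSF round trips preserve heights and pixel sizes", {
  td <- withr::local_tempdir()
  set.seed(2)
  hm <- heightmap(matrix(runif(64), 8, 8), 2.5, meta = list(Title = "t"))
  p <- file.path(td, "a.gsf")
  write_heightmap(hm, p)
  back <- read_heightmap(p)
  expect_lt(max(abs(back$heights - hm$heights)), 1e-6)
  expect_equal(back$pixel_size_x, 2.5, tolerance = 1e-9)
  # pixel size derived from XReal / XRes: 2.5 um / 256 px
  wide <- heightmap(matrix(0, 4, 256), 2500 / 256)
  p2 <- file.path(td, "b.gsf")
  write_heightmap(wide, p2)
  expect_equal(read_heightmap(p2)$pixel_size_x, 9.765625, tolerance = 1e-9)
  # constant map reads back with zero roughness
  expect_equal(rms_roughness(read_heightmap(p2)), 0)
})

test_that("malformed GSF input is rejected with a field name", {
  td <- withr::local_tempdir()
  bad <- file.path(td, "bad.gsf")
  writeBin(charToRaw("not a gsf\n"), bad)
  expect_error(read_heightmap(bad, format = "gsf"), "magic")
  # header missing XRes
  con <- file(file.path(td, "nox.gsf"), "wb")
  hdr <- charToRaw("Gwyddion Simple Field 1.0\nYRes = 2\n")
  writeBin(hdr, con); writeBin(raw(4 - length(hdr) %% 4), con)
  close(con)
  expect_error(read_heightmap(file.path(td, "nox.gsf"), format = "gsf"),
               "XRes")
})

test_that("CSV and TIFF round trips behave as documented", {
  td <- withr::local_tempdir()
  set.seed(3)
  hm <- heightmap(matrix(runif(256, 0, 80), 16, 16), 2.44)
  pc <- file.path(td, "m.csv")
  write_heightmap(hm, pc)
  expect_lt(max(abs(read_heightmap(pc)$heights - hm$heights)), 1e-6)
  # CSV without sidecar or pixel size fails
  file.remove(paste0(pc, ".json"))
  expect_error(read_heightmap(pc), "pixel size")
  expect_equal(read_heightmap(pc, pixel_size = 2.44)$pixel_size_x, 2.44)
  # TIFF: quantization step = range / 65535
  pt <- file.path(td, "m.tif")
  write_heightmap(hm, pt)
  q <- diff(range(hm$heights)) / 65535
  expect_lt(max(abs(read_heightmap(pt)$heights - hm$heights)), q)
})

test_that("non-finite pixels are rejected unless filled by line median", {
  td <- withr::local_tempdir()
  m <- matrix(1:16 + 0, 4, 4)
  hm <- heightmap(m, 1)
  p <- file.path(td, "n.csv")
  write_heightmap(hm, p)
  txt <- readLines(p)
  txt[2] <- sub("^[0-9.]+", "NaN", txt[2])
  writeLines(txt, p)
  expect_error(read_heightmap(p), "fill")
  filled <- read_heightmap(p, fill = TRUE)
  expect_true(all(is.finite(filled$heights)))
  expect_equal(filled$heights[2, 1], median(m[2, -1]))
})
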