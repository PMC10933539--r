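test_that("PLY round trips: ASCII at full precision, binary within float32", {
  set.seed(1)
  cl <- point_cloud(tibble::tibble(x = runif(500, -5, 5), y = runif(500, -5, 5),
                                   z = runif(500, 0, 50)))
  fa <- withr::local_tempfile(fileext = ".ply")
  write_cloud(cl, fa, format = "ply", binary = FALSE)
  back <- read_cloud(fa)
  expect_equal(back$x, cl$x, tolerance = 1e-15)
  expect_equal(back$z, cl$z, tolerance = 1e-15)

  fb <- withr::local_tempfile(fileext = ".ply")
  write_cloud(cl, fb, format = "ply", binary = TRUE)
  back <- read_cloud(fb)
  # float32 has ~7 significant digits; coordinates are O(50) m
  expect_equal(back$x, cl$x, tolerance = 1e-6)
  expect_lt(max(abs(back$z - cl$z)), 50 * 2^-23)
  expect_identical(nrow(back), nrow(cl)) # order and count preserved
})

test_that("a literal 3-point ASCII PLY parses to exactly those points", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "end_header", "0 0 0", "1 0 0", "0 1 0"), f)
  cl <- read_cloud(f)
  expect_equal(nrow(cl), 3)
  expect_equal(cl$x, c(0, 1, 0))
  expect_equal(cl$y, c(0, 0, 1))
  expect_equal(cl$z, c(0, 0, 0))
})

test_that("malformed files produce parse errors naming the location", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 1 1", "2 oops 2", "3 3 3"), f)
  expect_error(read_cloud(f), "line 3")

  f2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0", "1 1 1"), f2)
  expect_error(read_cloud(f2), "line 1")

  f3 <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 2",
               "property float x", "property float y", "property float z",
               "end_header", "0 0 0"), f3)
  expect_error(read_cloud(f3), "expects 2 rows")

  f4 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(character(0), f4)
  expect_error(read_cloud(f4), "empty cloud", class = "tlscarbon_empty_cloud")

  f5 <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("notply", "format ascii 1.0"), f5)
  expect_error(read_cloud(f5), "line 1")
})

test_that("XYZ round trip preserves coordinates and extra columns survive PLY", {
  cl <- point_cloud(tibble::tibble(x = c(0.1, 2.345), y = c(-1, 4), z = c(0, 9.87)))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_cloud(cl, f, format = "xyz")
  back <- read_cloud(f)
  expect_equal(back$x, cl$x, tolerance = 1e-8)
  expect_equal(back$y, cl$y, tolerance = 1e-8)
})

test_that("a minimal LAS file is read via header scale and offset", {
  f <- withr::local_tempfile(fileext = ".las")
  con <- file(f, open = "wb")
  hdr_size <- 227L
  writeChar("LASF", con, nchars = 4, eos = NULL)
  writeBin(raw(20), con)                                  # reserved + guids
  writeBin(as.raw(c(1L, 2L)), con)                        # version 1.2
  writeBin(raw(64), con)                                  # system id + software
  writeBin(raw(4), con)                                   # day/year
  writeBin(c(hdr_size), con, size = 2, endian = "little") # header size
  writeBin(hdr_size, con, size = 4, endian = "little")    # offset to points
  writeBin(0L, con, size = 4, endian = "little")          # n VLRs
  writeBin(as.raw(0L), con)                               # point format 0
  writeBin(20L, con, size = 2, endian = "little")         # record length
  writeBin(3L, con, size = 4, endian = "little")          # n points
  writeBin(raw(20), con)                                  # points by return
  writeBin(c(0.01, 0.01, 0.01), con, size = 8, endian = "little") # scales
  writeBin(c(100, 200, 0), con, size = 8, endian = "little")      # offsets
  writeBin(rep(0, 6), con, size = 8, endian = "little")   # min/max
  pts <- rbind(c(150L, 250L, 3050L), c(-100L, 0L, 10L), c(0L, 0L, 0L))
  for (i in 1:3) {
    writeBin(as.integer(pts[i, ]), con, size = 4, endian = "little")
    writeBin(raw(8), con) # rest of the 20-byte format-0 record
  }
  close(con)
  cl <- read_cloud(f, format = "las")
  expect_equal(cl$x, c(101.5, 99, 100))
  expect_equal(cl$y, c(202.5, 200, 200))
  expect_equal(cl$z, c(30.5, 0.1, 0))
})

test_that("tree tables compute ages and reject impossible rows by number", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,tree_id,planting_year,scan_year",
               "Benmore,B_T30,1863,2022",
               "Havering,H_T01,1870,2022"), f)
  tab <- read_tree_table(f)
  expect_equal(tab$age, c(159, 152))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,tree_id,planting_year,scan_year",
               "X,a,1900,2022", "X,b,2030,2022"), f2)
  expect_error(read_tree_table(f2), "row\\(s\\) 2")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,tree_id,planting_year", "X,a,1900"), f3)
  expect_error(read_tree_table(f3), "scan_year")

  f4 <- withr::local_tempfile(fileext = ".csv")
  file.create(f4)
  expect_error(read_tree_table(f4), "empty")
})

test_that("point_cloud validates coordinates", {
  expect_error(point_cloud(tibble::tibble(x = 1, y = 2)), "missing coordinate")
  expect_error(point_cloud(tibble::tibble(x = 1, y = 2, z = NA_real_)), "non-finite")
  expect_silent(point_cloud(matrix(runif(30), ncol = 3)))
})
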