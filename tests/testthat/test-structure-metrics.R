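test_that("tree height is the vertical extent, invariant to translation", {
  cl <- point_cloud(tibble::tibble(x = c(0, 0), y = c(0, 0), z = c(0, 54.87)))
  expect_equal(tree_height(cl), 54.87)
  flat <- point_cloud(tibble::tibble(x = 1:5, y = 1:5, z = rep(2, 5)))
  expect_equal(tree_height(flat), 0)
  shifted <- point_cloud(tibble::tibble(x = cl$x, y = cl$y, z = cl$z + 100))
  expect_equal(tree_height(shifted), 54.87)
  expect_error(tree_height(point_cloud(tibble::tibble(x = numeric(0), y = numeric(0),
                                                      z = numeric(0)))),
               class = "tlscarbon_empty_cloud")
})

test_that("slicing is half-open, relative to the lowest point, and counted", {
  cyl <- make_cylinder_cloud(h = 10, r = 1, spacing = 0.05)
  sec <- slice_cloud(cyl, 1.2, 1.4)
  # uniform ring ladder: expect total * 0.2/10 points, Poisson-ish bounds
  expected <- nrow(cyl) * 0.2 / 10
  expect_lt(abs(nrow(sec) - expected), 5 * sqrt(expected))
  expect_error(slice_cloud(cyl, 50, 51), class = "tlscarbon_insufficient_points")
  err <- tryCatch(slice_cloud(cyl, 50, 51), error = identity)
  expect_equal(err$n_points, 0)
  # boundary convention: a point exactly at z_high is excluded
  cl <- point_cloud(tibble::tibble(x = rep(0:4, 5) / 10, y = rep(0:4, each = 5) / 10,
                                   z = c(rep(1.0, 20), rep(1.5, 5))))
  expect_equal(nrow(slice_cloud(cl, 0, 0.5, min_points = 1)), 20)
})

test_that("DBH estimation matches cylinders exactly and cones within slice-taper bias", {
  cyl <- make_cylinder_cloud(h = 6, r = 1, spacing = 0.05)
  expect_equal(estimate_dbh(cyl), 2.0, tolerance = 1e-9)
  # rotational invariance
  expect_equal(estimate_dbh(rotate_z(cyl, 37)), estimate_dbh(cyl), tolerance = 1e-9)
  # cone with radius 0.16 at breast height (smallest-tree scale)
  h <- 17.44
  r13 <- 0.16
  cone <- make_cone_cloud(h = h, r0 = r13 * h / (h - 1.3), spacing = 0.02)
  expect_equal(estimate_dbh(cone), 0.32, tolerance = 0.01 * 0.32)
})

test_that("DTB equals DBH on cylinders and sits below DBH on flared trees", {
  cyl <- make_cylinder_cloud(h = 6, r = 0.8, spacing = 0.05)
  expect_equal(estimate_dtb(cyl), estimate_dbh(cyl), tolerance = 1e-9)
  g <- generate_tree_cloud(fast_spec(noise_sd = 0))
  expect_lt(estimate_dtb(g$cloud), estimate_dbh(g$cloud))
  expect_equal(estimate_dtb(g$cloud), g$truth$dtb_true, tolerance = 0.01)
  short <- make_cylinder_cloud(h = 3.5, r = 0.5, spacing = 0.05)
  expect_error(estimate_dtb(short), class = "tlscarbon_insufficient_points")
})

test_that("functional DBH reproduces closed-form hull diameters", {
  # dense circular boundary of radius 0.5 -> fDBH ~ 1.0
  th <- 2 * pi * (1:2000) / 2000
  circ <- point_cloud(tibble::tibble(x = 0.5 * cos(th), y = 0.5 * sin(th),
                                     z = rep(c(0, 1.3), 1000)))
  expect_equal(estimate_fdbh(circ), 1.0, tolerance = 1e-4)
  # ellipse semi-axes 0.6 x 0.4: area pi*a*b -> fDBH = 2 sqrt(ab)
  ell <- point_cloud(tibble::tibble(x = 0.6 * cos(th), y = 0.4 * sin(th),
                                    z = rep(c(0, 1.3), 1000)))
  expect_equal(estimate_fdbh(ell), 2 * sqrt(0.6 * 0.4), tolerance = 1e-4)
  # unit square corners: hull area 1 -> 2/sqrt(pi)
  sq <- point_cloud(tibble::tibble(x = c(0, 0, 1, 1, 0, 0.5), y = c(0, 0, 0, 1, 1, 0.5),
                                   z = c(0, rep(1.3, 5))))
  expect_equal(estimate_fdbh(sq, min_points = 1), 2 * sqrt(1 / pi), tolerance = 1e-9)
  # exact circular sections: fDBH converges to DBH with density
  expect_equal(estimate_fdbh(circ), estimate_dbh(circ, min_points = 3), tolerance = 1e-3)
})

test_that("crown volume is the 3-D hull volume and converges to closed forms", {
  cube <- point_cloud(tibble::tibble(x = rep(0:1, 4), y = rep(rep(0:1, each = 2), 2),
                                     z = rep(0:1, each = 4)))
  expect_equal(crown_volume(cube, crown_base = 0), 1.0, tolerance = 1e-12)
  # prolate spheroid semi-axes (2, 2, 8): V = (4/3) pi * 2 * 2 * 8
  set.seed(4)
  n <- 8000
  u <- runif(n, -1, 1); th <- runif(n, 0, 2 * pi)
  sph <- point_cloud(tibble::tibble(x = 2 * sqrt(1 - u^2) * cos(th),
                                    y = 2 * sqrt(1 - u^2) * sin(th),
                                    z = 8 * u))
  v <- crown_volume(sph, crown_base = 0)
  expect_equal(v, 4 / 3 * pi * 2 * 2 * 8, tolerance = 0.01)
  expect_lt(v, 4 / 3 * pi * 2 * 2 * 8) # inscribed hull underestimates
  expect_error(crown_volume(cube, crown_base = 5), class = "tlscarbon_degenerate")
  flat <- point_cloud(tibble::tibble(x = runif(50), y = runif(50), z = rep(1, 50)))
  expect_error(crown_volume(flat, crown_base = 0), class = "tlscarbon_degenerate")
})

test_that("diameters, height and crown volume are rigid-motion invariant", {
  # ring spacing chosen so no ring sits exactly on a slice boundary
  g <- generate_tree_cloud(fast_spec(noise_sd = 0, point_spacing = 0.097))
  cl <- g$cloud
  moved <- rotate_z(cl, 123)
  moved <- point_cloud(tibble::tibble(x = moved$x + 50, y = moved$y - 20,
                                      z = moved$z + 7))
  expect_equal(tree_height(moved), tree_height(cl), tolerance = 1e-9)
  expect_equal(estimate_dbh(moved), estimate_dbh(cl), tolerance = 1e-8)
  expect_equal(estimate_fdbh(moved), estimate_fdbh(cl), tolerance = 1e-8)
  expect_equal(crown_volume(moved, crown_base = 8), crown_volume(cl, crown_base = 8),
               tolerance = 1e-8)
})

test_that("compute_all_metrics populates everything near truth and degrades gracefully", {
  g <- generate_tree_cloud(fast_spec(seed = 5L))
  m <- compute_all_metrics(g$cloud, tree_id = "fix1",
                           volume_config = list(n_repeats = 3L, seed = 2L))
  expect_equal(m$tree_id, "fix1")
  expect_length(m$issues[[1]], 0)
  expect_equal(m$h_m, g$truth$height_true, tolerance = 0.005)
  expect_equal(m$dbh_m, g$truth$dbh_true, tolerance = 0.02)
  expect_equal(m$dtb_m, g$truth$dtb_true, tolerance = 0.02)
  expect_equal(m$cv_m3, g$truth$crown_volume_true, tolerance = 0.1)
  expect_equal(m$v_m3, g$truth$woody_volume_true, tolerance = 0.05)
  expect_gt(m$v_sd_m3, 0)

  # tiny cloud: height still reported, every other metric flagged missing
  small <- point_cloud(tibble::tibble(x = runif(50), y = runif(50), z = runif(50, 0, 10)))
  m2 <- compute_all_metrics(small)
  expect_equal(m2$h_m, tree_height(small))
  expect_true(all(is.na(c(m2$dbh_m, m2$dtb_m, m2$fdbh_m, m2$cv_m3, m2$v_m3))))
  expect_true(all(grepl("insufficient points", m2$issues[[1]])))

  # determinism on a fixed cloud
  m3 <- compute_all_metrics(g$cloud, tree_id = "fix1",
                            volume_config = list(n_repeats = 3L, seed = 2L))
  expect_identical(m[, -which(names(m) == "issues")], m3[, -which(names(m3) == "issues")])
})
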