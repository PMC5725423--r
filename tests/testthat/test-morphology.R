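test_that("area, centroid and COM vector match closed forms", {
  # circle centred on the soma: vanishing COM vector, area pi r^2
  circ <- gen_morphology(arbor_params(mean_radius_um = 100))
  com <- compute_com(circ)
  expect_lt(com$com_vector_length_um, 1e-9 * 100)
  expect_equal(com$area_um2, pi * 100^2, tolerance = 1e-4)

  # unit square with the soma at a corner
  sq <- arbor_polygon_from_perimeter(
    rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), soma_xy = c(0, 0), n = 1000)
  com <- compute_com(sq)
  expect_equal(com$area_um2, 1, tolerance = 1e-12)
  expect_equal(com$com_xy_um, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(com$com_vector_length_um, sqrt(0.5), tolerance = 1e-9)
  expect_equal(com$com_vector_angle_deg, 45, tolerance = 1e-9)

  # ventrally offset synthetic arbor: recovered within 2%
  v <- gen_morphology(arbor_params(com_offset_um = c(0, -145)))
  com <- compute_com(v)
  expect_equal(com$com_vector_length_um, 145, tolerance = 0.02)
  expect_equal(com$com_vector_angle_deg, 270, tolerance = 0.5)
})

test_that("perimeter resampling is uniform in arc length", {
  sq <- arbor_polygon_from_perimeter(
    rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), soma_xy = c(0.5, 0.5), n = 8)
  seg <- sqrt(rowSums((rbind(sq$perimeter_um[-1, ], sq$perimeter_um[1, ]) -
                         sq$perimeter_um)^2))
  expect_equal(seg, rep(0.5, 8), tolerance = 1e-9)

  # 1000 points on the unit square: 250 per side (+/- 1)
  sq2 <- arbor_polygon_from_perimeter(
    rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), soma_xy = c(0.5, 0.5), n = 1000)
  on_bottom <- sum(abs(sq2$perimeter_um[, 2]) < 1e-9)
  expect_lte(abs(on_bottom - 250), 1)
})

test_that("DOI matches symmetry limits and the dense-summation oracle", {
  circ <- gen_morphology(arbor_params(mean_radius_um = 80))
  expect_lt(compute_doi(circ)$doi, 1e-9)

  # two antipodal clusters (a degenerate segment-like outline): DOI -> 1
  phi <- c(seq(-0.01, 0.01, length.out = 50),
           pi + seq(-0.01, 0.01, length.out = 50))
  seg <- cbind(100 * cos(phi), 100 * sin(phi) * 0.001)
  poly <- arbor_polygon_from_perimeter(seg, soma_xy = c(0, 0), n = 200)
  expect_gt(compute_doi(poly)$doi, 0.99)

  # 2:1 ellipse at 30 degrees against the dense arc-length oracle
  ell <- gen_morphology(arbor_params(mean_radius_um = 100, elongation = 2,
                                     orientation_deg = 30))
  doi <- compute_doi(ell)
  oracle <- oracle_ellipse_doi(100 * sqrt(2), 100 / sqrt(2), 30)
  expect_equal(doi$doi, oracle$doi, tolerance = 1e-4)
  expect_equal(doi$doi_angle_deg, 30, tolerance = 0.5)
})

test_that("DOI grows with elongation and vanishes for symmetric arbors", {
  dois <- vapply(c(1, 1.3, 1.8, 2.5, 4), function(e) {
    compute_doi(gen_morphology(arbor_params(mean_radius_um = 100,
                                            elongation = e)))$doi
  }, numeric(1))
  expect_lt(dois[1], 0.05)
  expect_true(all(diff(dois) > 0))

  # jagged but circular arbors stay effectively isotropic
  set.seed(21)
  for (s in 1:5) {
    j <- gen_morphology(arbor_params(mean_radius_um = 120,
                                     jaggedness_sd_um = 3, seed = s))
    expect_lt(compute_doi(j)$doi, 0.05)
  }
})

test_that("morphometrics are rotation-equivariant and scale-covariant", {
  set.seed(17)
  for (i in 1:20) {
    xy <- random_star_polygon(seed = 1000 + i)
    soma <- c(5, -8)
    p0 <- arbor_polygon_from_perimeter(xy, soma, n = 400)
    m0 <- compute_com(p0); d0 <- compute_doi(p0)
    delta <- runif(1, 5, 175)
    p_rot <- arbor_polygon_from_perimeter(rotate_xy(xy, delta),
                                          rotate_xy(rbind(soma), delta)[1, ],
                                          n = 400)
    m1 <- compute_com(p_rot); d1 <- compute_doi(p_rot)
    expect_equal(m1$area_um2, m0$area_um2, tolerance = 1e-6)
    expect_equal(m1$com_vector_length_um, m0$com_vector_length_um,
                 tolerance = 1e-6)
    expect_equal(d1$doi, d0$doi, tolerance = 1e-6)
    if (d0$doi > 1e-3)
      expect_lt(orientation_angle_difference(d1$doi_angle_deg,
                                             d0$doi_angle_deg + delta), 0.1)
    s <- runif(1, 0.2, 4)
    p_sc <- arbor_polygon_from_perimeter(xy * s, soma * s, n = 400)
    m2 <- compute_com(p_sc); d2 <- compute_doi(p_sc)
    expect_equal(m2$area_um2, s^2 * m0$area_um2, tolerance = 1e-6)
    expect_equal(m2$com_vector_length_um, s * m0$com_vector_length_um,
                 tolerance = 1e-6)
    expect_equal(d2$doi, d0$doi, tolerance = 1e-9)
  }
})

test_that("DOI is independent of the soma position", {
  xy <- random_star_polygon(seed = 77)
  a <- compute_doi(arbor_polygon_from_perimeter(xy, c(0, 0), n = 300))
  b <- compute_doi(arbor_polygon_from_perimeter(xy, c(120, -40), n = 300))
  expect_identical(a, b)
})

test_that("outline fitting covers the point cloud and converges to the disc", {
  # square corners: hull recovers the square
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  poly <- arbor_polygon(pts, soma_xy = c(0.5, 0.5), n = 1000)
  expect_equal(compute_com(poly)$area_um2, 1, tolerance = 1e-9)

  # dense disc samples: hull area approaches the disc area
  set.seed(12)
  r <- 100 * sqrt(runif(4000)); a <- runif(4000, 0, 2 * pi)
  disc <- cbind(r * cos(a), r * sin(a))
  hull <- arbor_polygon(disc, soma_xy = c(0, 0))
  expect_equal(compute_com(hull)$area_um2, pi * 100^2, tolerance = 0.02)

  # the radial outline hugs a concave (crescent-like) field better than
  # the hull
  phi <- seq(0.4 * pi, 1.6 * pi, length.out = 2000)
  cres <- cbind(cos(phi) * runif(2000, 80, 100),
                sin(phi) * runif(2000, 80, 100))
  hull_a <- compute_com(arbor_polygon(cres, c(0, 0)))$area_um2
  alpha_a <- compute_com(arbor_polygon(cres, c(0, 0),
                                       method = "alpha_outline"))$area_um2
  expect_lt(alpha_a, hull_a)

  expect_error(arbor_polygon(cbind(1:5, 2 * (1:5)), c(0, 0)), "collinear")
})

test_that("SWC files round-trip and malformed input is reported by line", {
  dir <- withr::local_tempdir()
  arb <- gen_morphology(arbor_params(mean_radius_um = 90,
                                     com_offset_um = c(30, -20),
                                     n_perimeter_points = 100))
  p <- file.path(dir, "arbor.swc")
  write_swc(arb, p)
  back <- read_swc(p)
  expect_equal(back$soma_xy, arb$soma_xy_um, tolerance = 1e-6)
  expect_equal(unname(back$dendrite_xy), unname(arb$perimeter_um),
               tolerance = 1e-6)

  writeLines(c("# minimal", "1 1 0 0 0 1 -1", "2 3 10 0 0 1 1",
               "3 3 0 10 0 1 2"), file.path(dir, "mini.swc"))
  mini <- read_swc(file.path(dir, "mini.swc"))
  expect_equal(nrow(mini$dendrite_xy), 2)
  expect_equal(mini$soma_xy, c(0, 0))

  writeLines(c("1 1 0 0 0 1 -1", "2 3 10 0 0 1"), file.path(dir, "bad.swc"))
  expect_error(read_swc(file.path(dir, "bad.swc")), "line 2")

  writeLines(c("1 1 0 0 0 1 -1", "2 3 1 1 0 1 9"), file.path(dir, "orph.swc"))
  expect_error(read_swc(file.path(dir, "orph.swc")), "parent 9")

  writeLines(c("1 1 0 0 0 1 -1", "2 2 1 1 0 1 1"), file.path(dir, "nod.swc"))
  expect_error(read_swc(file.path(dir, "nod.swc")), "no dendrite")
})
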