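test_that("polygon area matches closed forms and ignores orientation", {
  sq <- planar_contour(plane_xy(), rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(polygon_area(sq), 1)

  n <- 64; r <- 20
  expect_equal(polygon_area(circle_contour(r, n)),
               n / 2 * r^2 * sin(2 * pi / n), tolerance = 1e-12)

  pts <- rbind(c(0, 0), c(3, 1), c(2, 4), c(-1, 2))
  cw <- planar_contour(plane_xy(), pts[rev(seq_len(nrow(pts))), ])
  ccw <- planar_contour(plane_xy(), pts)
  expect_identical(polygon_area(cw), polygon_area(ccw))

  expect_error(planar_contour(plane_xy(), rbind(c(0, 0), c(1, 1))),
               "invalid-geometry")
  expect_error(planar_contour(plane_xy(), rbind(c(0, 0), c(1, 1), c(2, 2))),
               "invalid-geometry")
})

test_that("polygon centroid is exact for symmetric and composite shapes", {
  sq <- planar_contour(plane_xy(5), rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(polygon_centroid(sq), c(0.5, 0.5, 5), tolerance = 1e-12)

  circ <- circle_contour(7, 128, center = c(10, -5))
  expect_equal(polygon_centroid(circ), c(10, -5, 0), tolerance = 1e-6)

  ## L-shape = 2x1 rectangle at (1, 0.5) plus 1x1 square at (0.5, 1.5):
  ## centroid (2*1 + 1*0.5, 2*0.5 + 1*1.5) / 3 = (5/6, 5/6)
  ell <- planar_contour(plane_xy(), rbind(c(0, 0), c(2, 0), c(2, 1),
                                          c(1, 1), c(1, 2), c(0, 2)))
  expect_equal(polygon_centroid(ell), c(5 / 6, 5 / 6, 0), tolerance = 1e-12)
})

test_that("area is rigid-motion invariant and scales quadratically", {
  set.seed(42)
  for (i in 1:20) {
    ct <- random_star_polygon(14)
    a0 <- polygon_area(ct)
    moved <- transform_contour(ct, rotation_xyz(0.3, -1.1, 2.0), c(12, -7, 30))
    expect_equal(polygon_area(moved), a0, tolerance = 1e-12)
    expect_equal(polygon_area(scale_contour(ct, 2.5)), a0 * 2.5^2,
                 tolerance = 1e-12)
  }
})

test_that("plane-contour intersection handles circles, disjoint planes and concavities", {
  circ <- circle_contour(20, 256)
  pts <- plane_contour_intersection(circ, plane_yz(0))
  expect_equal(nrow(pts), 2L)
  expect_equal(pts[, 2L], c(-20, 20), tolerance = 1e-2)  # 256-gon chord ends
  expect_equal(pts[, 1L], c(0, 0), tolerance = 1e-9)

  expect_identical(nrow(plane_contour_intersection(circ, plane_yz(25))), 0L)

  expect_error(plane_contour_intersection(circ, plane_xy(1)), "no-intersection")

  ## kidney-shaped non-convex polygon: a cut through the concavity gives 4
  ## crossings, verified against the brute-force per-edge oracle
  kidney <- planar_contour(plane_xy(), rbind(
    c(0, 0), c(4, -1), c(8, 0), c(9, 3), c(7, 5), c(5, 3), c(4, 2.5),
    c(3, 3), c(1, 5), c(-1, 3), c(-1, 1), c(-0.5, 0.3)))
  cut <- image_plane(c(0, 3.2, 0), c(0, 0, 1), c(1, 0, 0))  # plane y = 3.2
  got <- plane_contour_intersection(kidney, cut)
  oracle <- brute_force_plane_crossings(kidney, cut)
  expect_equal(nrow(got), 4L)
  expect_equal(nrow(oracle), 4L)
  expect_equal(sort(got[, 1L]), sort(oracle[, 1L]), tolerance = 1e-9)
})

test_that("intersection agrees with the brute-force edge oracle on random polygons", {
  set.seed(7)
  n_checked <- 0L
  for (i in 1:1000) {
    ct <- random_star_polygon(n = sample(6:24, 1L))
    x0 <- stats::runif(1, -12, 12)
    cut <- plane_yz(x0)
    got <- plane_contour_intersection(ct, cut)
    oracle <- brute_force_plane_crossings(ct, cut)
    expect_equal(nrow(got), nrow(oracle))
    if (nrow(got) > 0L) {
      o <- order(oracle[, 2L])   # sort along y = intersection line
      expect_equal(got[, 2L], oracle[o, 2L], tolerance = 1e-9)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 500L)
})

test_that("chord_through returns the outermost pair", {
  circ <- circle_contour(20, 4096)
  expect_equal(chord_through(circ, plane_yz(0))$length, 40, tolerance = 1e-4)
  expect_equal(chord_through(circ, plane_yz(12))$length,
               2 * sqrt(400 - 144), tolerance = 1e-3)

  ## papillary-style indentation: 4 crossings; outermost pair must be at
  ## least as long as every other crossing pair's separation
  kidney <- planar_contour(plane_xy(), rbind(
    c(0, 0), c(4, -1), c(8, 0), c(9, 3), c(7, 5), c(5, 3), c(4, 2.5),
    c(3, 3), c(1, 5), c(-1, 3), c(-1, 1), c(-0.5, 0.3)))
  cut <- image_plane(c(0, 3.2, 0), c(0, 0, 1), c(1, 0, 0))
  pts <- plane_contour_intersection(kidney, cut)
  seps <- as.numeric(dist(pts[, 1L]))
  expect_equal(chord_through(kidney, cut)$length, max(seps), tolerance = 1e-9)

  expect_error(chord_through(circ, plane_yz(30)), "missing-chord")
})

test_that("slab clipping is exact on rectangles and matches quadrature on ellipses", {
  rect <- planar_contour(plane_xy(), rbind(c(-20, -30), c(20, -30),
                                           c(20, 30), c(-20, 30)))
  up <- image_plane(c(0, 10, 0), c(0, 0, 1), c(1, 0, 0))   # plane y = 10
  lo <- image_plane(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))    # plane y = 0
  clipped <- clip_contour_between_planes(rect, up, lo)
  expect_equal(polygon_area(clipped), 400, tolerance = 1e-9)

  ## 40 x 60 ellipse clipped between heights 0 and 10: analytic zone area
  th <- 2 * pi * (0:2047) / 2048
  ell <- planar_contour(plane_xy(), cbind(20 * cos(th), 30 * sin(th)))
  zone <- polygon_area(clip_contour_between_planes(ell, up, lo))
  ref <- stats::integrate(function(y) 2 * 20 * sqrt(1 - (y / 30)^2), 0, 10,
                          rel.tol = 1e-10)$value
  expect_equal(zone, ref, tolerance = 1e-4)

  far <- image_plane(c(0, 50, 0), c(0, 0, 1), c(1, 0, 0))
  farther <- image_plane(c(0, 60, 0), c(0, 0, 1), c(1, 0, 0))
  expect_error(clip_contour_between_planes(rect, far, farther), "empty-region")
})

test_that("clipping a contour into slabs partitions its area", {
  set.seed(11)
  for (i in 1:25) {
    ct <- random_star_polygon(18)
    cuts <- sort(stats::runif(3, -9, 9))
    bounds <- c(-16, cuts, 16)
    total <- 0
    for (k in seq_len(length(bounds) - 1L)) {
      up <- image_plane(c(0, bounds[k + 1L], 0), c(0, 0, 1), c(1, 0, 0))
      lo <- image_plane(c(0, bounds[k], 0), c(0, 0, 1), c(1, 0, 0))
      ## non-convex sections may be disconnected, so measure via the
      ## bridge-tolerant area path
      a <- tryCatch(trapvol:::clip_area_between_planes(ct, up, lo),
                    error = function(e) 0)
      total <- total + a
    }
    expect_equal(total, polygon_area(ct), tolerance = 1e-6)
  }
})

test_that("line-plane angles cover the canonical cases", {
  pl <- plane_xy()
  expect_equal(angle_plane_to_line(line_segment3(c(0, 0, 0), c(0, 0, 5)), pl),
               pi / 2)
  expect_equal(angle_plane_to_line(line_segment3(c(0, 0, 0), c(3, 1, 0)), pl), 0)
  expect_equal(angle_plane_to_line(line_segment3(c(0, 0, 0), c(1, 0, 1)), pl),
               pi / 4, tolerance = 1e-12)
  expect_error(angle_plane_to_line(line_segment3(c(1, 1, 1), c(1, 1, 1)), pl),
               "invalid-geometry")
})
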