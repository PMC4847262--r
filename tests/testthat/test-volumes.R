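test_that("modified Simpson sums disc volumes with the extent rule", {
  one <- contour_stack(list(circle_contour(20, 4096, slice_index = 0L)),
                       slice_thickness = 8, gap = 2)
  est <- msimp_volume(one)
  expect_equal(est$total, pi * 400 * 10 / 1000, tolerance = 1e-5)

  ## cylinder cut into 12 discs tiling the height exactly: zero error
  H <- 50; r <- 20
  zs <- seq(H / 2 - H / 24, -H / 2 + H / 24, length.out = 12)
  st <- cylinder_stack(r = r, z_positions = zs, lax_z = c(-H / 2, H / 2),
                       n = 4096)
  expect_equal(msimp_volume(st)$total, pi * r^2 * H / 1000, tolerance = 1e-5)

  ## non-uniform retained planes: each disc extends to the next plane,
  ## the most apical disc gets the mean extent ((10 + 20) / 2 = 15)
  st3 <- cylinder_stack(r = r, z_positions = c(30, 20, 0), lax_z = c(-5, 35),
                        n = 4096)
  expect_equal(msimp_volume(st3)$total, pi * r^2 * (10 + 20 + 15) / 1000,
               tolerance = 1e-5)

  ## single slice with no extent metadata is a configuration error
  bare <- contour_stack(list(circle_contour(20, 64, slice_index = 0L)))
  expect_error(msimp_volume(bare), "configuration")
})

test_that("trapezoidal chunk volume reproduces hand-computed values", {
  cyl_chunk <- trapvol:::new_chunk(1L, "interior", 1256.637, 1256.637, 400,
                                   40, 40, 0)
  expect_equal(trapezoidal_chunk_volume(cyl_chunk), 12.56637, tolerance = 1e-6)

  ap <- trapvol:::new_chunk(5L, "apical", 1256.637, 0, 200, 40, 0, 0)
  expect_equal(trapezoidal_chunk_volume(ap), 200 * 1256.637 / 80 / 1000,
               tolerance = 1e-9)

  ## the apical formula is the d_low = 0, A_low = 0 specialisation of the
  ## interior formula once the triangular LAX section is halved (a
  ## triangle has half the area of the trapezoid with its base and height)
  tri_as_interior <- trapvol:::new_chunk(5L, "interior", 1256.637, 0, 100,
                                         40, 0, 0)
  expect_equal(trapezoidal_chunk_volume(ap),
               trapezoidal_chunk_volume(tri_as_interior), tolerance = 1e-12)

  degen <- trapvol:::new_chunk(1L, "interior", 100, 100, 50, 0, 0, 0)
  expect_error(trapezoidal_chunk_volume(degen), "degenerate-chunk")
})

test_that("trapezoidal volume is exact on cylinders and accurate on ellipsoids", {
  ## analytic cylinder stack at 64-vertex contours
  st <- cylinder_stack(r = 20, z_positions = seq(25, -25, length.out = 6),
                       lax_z = c(-25, 25), n = 64)
  est <- suppressWarnings(trapezoidal_volume(st))
  truth <- pi * 400 * 50 / 1000
  expect_lt(abs(est$total - truth) / truth, 0.005)
  expect_equal(est$total, sum(est$per_chunk), tolerance = 1e-12)

  ## prolate ellipsoid (20, 20, 45): within 2.5 % of 4/3 pi a b c
  ell <- phantom_spec("ellipsoid", a = 20, b = 20, c = 45)
  st2 <- reslice(ell, sax_count = 12)
  v2 <- trapezoidal_volume(st2)$total
  expect_lt(abs(v2 - 75.39822) / 75.39822, 0.025)

  ## basal virtual toggle adds exactly the mirrored chunk volume
  stb <- cylinder_stack(r = 20, z_positions = c(20, 10, 0, -10, -20),
                        lax_z = c(-30, 28))
  v_off <- trapezoidal_volume(stb)$total
  v_on <- trapezoidal_volume(stb, include_basal_virtual = TRUE)$total
  bv <- build_chunks(stb, include_basal_virtual = TRUE)[[1L]]
  expect_equal(v_on - v_off, trapezoidal_chunk_volume(bv), tolerance = 1e-12)
})

test_that("numeric wedge integration agrees with the closed form", {
  ## circular SAX: constant integrand, forms agree to discretisation error
  st <- cylinder_stack(r = 20, z_positions = seq(20, -20, length.out = 5),
                       lax_z = c(-30, 30), n = 1024)
  vc <- trapezoidal_volume(st)$total
  vi <- trapezoidal_integral_volume(st, n_theta = 360)$total
  expect_lt(abs(vi - vc) / vc, 1e-4)

  ## elliptical SAX (40 x 60 mm): within 3 %
  th <- 2 * pi * (0:255) / 256
  sax <- lapply(0:2, function(j)
    planar_contour(plane_xy(10 - 10 * j), cbind(20 * cos(th), 30 * sin(th)),
                   slice_index = j))
  lax_plane <- image_plane(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  rect <- rbind(c(20, -15), c(20, 15), c(-20, 15), c(-20, -15))
  ste <- contour_stack(sax, planar_contour(lax_plane, rect),
                       slice_thickness = 10, gap = 0)
  ve_c <- suppressWarnings(trapezoidal_volume(ste))$total
  ve_i <- suppressWarnings(trapezoidal_integral_volume(ste, n_theta = 360))$total
  expect_lt(abs(ve_i - ve_c) / ve_c, 0.03)

  ## quadrature convergence on a smooth phantom; dense SAX sampling keeps
  ## polygon-vertex kinks below the quadrature error
  ell <- phantom_spec("ellipsoid", a = 20, b = 25, c = 45)
  stq <- reslice(ell, sax_count = 6, n_vertices = 256)
  v180 <- trapezoidal_integral_volume(stq, n_theta = 180)$total
  v360 <- trapezoidal_integral_volume(stq, n_theta = 360)$total
  expect_lt(abs(v360 - v180) / v360, 1e-4)

  expect_error(trapezoidal_integral_volume(st, n_theta = 4), "resolution")
})

test_that("classical models reproduce their closed forms", {
  expect_equal(classical_volume("teichholz", D = 40), 70, tolerance = 1e-12)
  expect_equal(classical_volume("hemisphere-cylinder", A = 1256.64, L = 90),
               5 / 6 * 1256.64 * 90 / 1000, tolerance = 1e-12)

  ## biplane on a true spheroid recovers 4/3 pi a b^2 exactly
  a <- 45; b <- 21
  expect_equal(classical_volume("biplane", A1 = pi * a * b, A2 = pi * a * b,
                                L = 2 * a),
               4 / 3 * pi * a * b^2 / 1000, tolerance = 1e-12)
  ## single-plane on a sphere recovers 4/3 pi r^3
  r <- 30
  expect_equal(classical_volume("single-plane", A = pi * r^2, L = 2 * r),
               4 / 3 * pi * r^3 / 1000, tolerance = 1e-12)

  expect_error(classical_volume("frustum", A = 1), "arg")
  expect_error(classical_volume("teichholz", D = -1), "positive")
  expect_error(classical_volume("biplane", A1 = 10, L = 5), "needs")
})

test_that("every estimator scales as s^3 under uniform scaling", {
  st <- reslice(phantom_cohort(1, seed = 3)[[1L]], sax_count = 6)
  s <- 2
  st2 <- scale_stack(st, s)
  expect_equal(trapezoidal_volume(st2)$total,
               s^3 * trapezoidal_volume(st)$total, tolerance = 1e-12)
  expect_equal(msimp_volume(st2)$total, s^3 * msimp_volume(st)$total,
               tolerance = 1e-12)
  expect_equal(trapezoidal_integral_volume(st2, n_theta = 90)$total,
               s^3 * trapezoidal_integral_volume(st, n_theta = 90)$total,
               tolerance = 1e-12)
})
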