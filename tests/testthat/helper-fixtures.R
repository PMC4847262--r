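## Shared fixtures: all built in code, no files.

plane_xy <- function(z = 0) image_plane(c(0, 0, z), c(1, 0, 0), c(0, 1, 0))

## plane with normal +x (for cutting): contains y and z axes
plane_yz <- function(x = 0) image_plane(c(x, 0, 0), c(0, 1, 0), c(0, 0, 1))

circle_contour <- function(r = 20, n = 64, center = c(0, 0), plane = plane_xy(),
                           ...) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  planar_contour(plane, cbind(center[1L] + r * cos(th), center[2L] + r * sin(th)),
                 ...)
}

## analytic cylinder stack: circular SAX slices + exact rectangular LAX in
## the x-z plane.  Slice positions run base (z_top) to apex.
cylinder_stack <- function(r = 20, z_positions = c(20, 10, 0, -10, -20),
                           lax_z = c(-25, 25), n = 512) {
  sax <- lapply(seq_along(z_positions), function(i)
    circle_contour(r, n, plane = plane_xy(z_positions[i]), slice_index = i - 1L))
  lax_plane <- image_plane(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1))
  rect <- rbind(c(r, lax_z[1L]), c(r, lax_z[2L]), c(-r, lax_z[2L]), c(-r, lax_z[1L]))
  lax <- planar_contour(lax_plane, rect)
  contour_stack(sax, lax, slice_thickness = abs(diff(z_positions))[1L], gap = 0)
}

## random star-shaped (hence simple) polygon in a given plane; jittered
## regular angles keep every angular gap below pi so the origin stays
## interior and edges cannot cross
random_star_polygon <- function(n = 16, r_base = 10, plane = plane_xy()) {
  th <- 2 * pi * (seq_len(n) - 1L) / n + stats::runif(n, 0, 0.8 * 2 * pi / n)
  r <- r_base * stats::runif(n, 0.5, 1.5)
  planar_contour(plane, cbind(r * cos(th), r * sin(th)))
}

## independent brute-force oracle: intersect each polygon edge with a plane
## by direct 3D parametric solution (no snapping, no sorting logic shared
## with the implementation)
brute_force_plane_crossings <- function(contour, cutting) {
  p3 <- contour_points_3d(contour)
  n <- nrow(p3)
  hits <- matrix(numeric(0), ncol = 3L)
  for (i in seq_len(n)) {
    a <- p3[i, ]; b <- p3[if (i == n) 1L else i + 1L, ]
    da <- sum((a - cutting$origin) * cutting$normal)
    db <- sum((b - cutting$origin) * cutting$normal)
    if ((da < 0 && db >= 0) || (da >= 0 && db < 0)) {
      t <- da / (da - db)
      hits <- rbind(hits, a + t * (b - a))
    }
  }
  hits
}

scale_contour <- function(ct, s) {
  pl <- ct$plane
  planar_contour(image_plane(pl$origin * s, pl$axis_u, pl$axis_v),
                 ct$points * s, surface = ct$surface, phase = ct$phase,
                 slice_index = ct$slice_index)
}

scale_stack <- function(stack, s) {
  stack$sax <- lapply(stack$sax, scale_contour, s = s)
  if (!is.null(stack$lax)) stack$lax <- scale_contour(stack$lax, s)
  if (!is.null(stack$slice_thickness))
    stack$slice_thickness <- stack$slice_thickness * s
  stack$gap <- stack$gap * s
  stack
}

rotation_xyz <- function(ax, ay, az) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}
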