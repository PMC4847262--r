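## Planar / 3D geometry kernel: oriented image planes, closed planar
## contours in patient coordinates (mm), plane-polygon intersection and
## slab clipping.  Everything downstream (chunk decomposition, volume
## models, phantom reslicing) is built on these primitives.

#' Construct an oriented image plane
#'
#' An image plane is a point in patient space (mm) plus an orthonormal
#' in-plane frame \code{(axis_u, axis_v)}; the plane normal is
#' \code{axis_u x axis_v} (right-handed).  This mirrors the DICOM-style
#' "position + orientation" specification of an MR slice without binding
#' to DICOM itself.
#'
#' @param origin numeric length-3, plane origin in patient coordinates (mm).
#' @param axis_u,axis_v numeric length-3 in-plane direction vectors; they are
#'   normalised, and \code{axis_v} is re-orthogonalised against
#'   \code{axis_u} if needed (must not be collinear).
#' @return an object of class \code{image_plane} with fields \code{origin},
#'   \code{axis_u}, \code{axis_v}, \code{normal}.
#' @examples
#' pl <- image_plane(c(0, 0, 10), c(1, 0, 0), c(0, 1, 0))
#' pl$normal  # c(0, 0, 1)
#' @export
image_plane <- function(origin, axis_u, axis_v) {
  origin <- as.numeric(origin)
  axis_u <- as.numeric(axis_u)
  axis_v <- as.numeric(axis_v)
  if (length(origin) != 3L || length(axis_u) != 3L || length(axis_v) != 3L)
    stop("image_plane: origin, axis_u, axis_v must be length-3 numeric")
  nu <- sqrt(sum(axis_u^2))
  if (nu < 1e-12) stop("image_plane: axis_u is degenerate")
  u <- axis_u / nu
  v <- axis_v - sum(axis_v * u) * u
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("image_plane: axis_v collinear with axis_u")
  v <- v / nv
  structure(
    list(origin = origin, axis_u = u, axis_v = v, normal = cross3(u, v)),
    class = "image_plane"
  )
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

unit3 <- function(x) {
  n <- sqrt(sum(x^2))
  if (n < 1e-12) stop("zero-length vector cannot be normalised")
  x / n
}

#' @export
print.image_plane <- function(x, ...) {
  cat("image_plane: origin (", paste(signif(x$origin, 6), collapse = ", "),
      ") mm, normal (", paste(signif(x$normal, 4), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

## signed distance (mm) of 3D points (n x 3) from a plane
plane_signed_distance <- function(plane, pts3) {
  pts3 <- matrix(pts3, ncol = 3L)
  (pts3[, 1L] - plane$origin[1L]) * plane$normal[1L] +
  (pts3[, 2L] - plane$origin[2L]) * plane$normal[2L] +
  (pts3[, 3L] - plane$origin[3L]) * plane$normal[3L]
}

## map in-plane 2D points (n x 2) to 3D patient coordinates (n x 3)
plane_to_world <- function(plane, pts2) {
  pts2 <- matrix(pts2, ncol = 2L)
  cbind(plane$origin[1L] + pts2[, 1L] * plane$axis_u[1L] + pts2[, 2L] * plane$axis_v[1L],
        plane$origin[2L] + pts2[, 1L] * plane$axis_u[2L] + pts2[, 2L] * plane$axis_v[2L],
        plane$origin[3L] + pts2[, 1L] * plane$axis_u[3L] + pts2[, 2L] * plane$axis_v[3L])
}

## project 3D points onto a plane's (u, v) frame
world_to_plane <- function(plane, pts3) {
  pts3 <- matrix(pts3, ncol = 3L)
  d1 <- pts3[, 1L] - plane$origin[1L]
  d2 <- pts3[, 2L] - plane$origin[2L]
  d3 <- pts3[, 3L] - plane$origin[3L]
  cbind(d1 * plane$axis_u[1L] + d2 * plane$axis_u[2L] + d3 * plane$axis_u[3L],
        d1 * plane$axis_v[1L] + d2 * plane$axis_v[2L] + d3 * plane$axis_v[3L])
}

shoelace_signed_area <- function(pts2) {
  x <- pts2[, 1L]; y <- pts2[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

## simple-polygon check: no two non-adjacent edges intersect.  O(n^2)
## pairs but the inner sweep over j is vectorised; contours here are at
## most a few hundred vertices.
polygon_is_simple <- function(pts2, tol = 1e-9) {
  n <- nrow(pts2)
  if (n < 3L) return(FALSE)
  a <- pts2
  b <- pts2[c(2:n, 1L), , drop = FALSE]
  e <- b - a
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    js <- seq.int(i + 2L, jmax)
    d1x <- e[i, 1L]; d1y <- e[i, 2L]
    d2x <- e[js, 1L]; d2y <- e[js, 2L]
    dpx <- a[js, 1L] - a[i, 1L]; dpy <- a[js, 2L] - a[i, 2L]
    den <- d1x * d2y - d1y * d2x
    ok <- abs(den) > tol
    if (any(ok)) {
      tt <- (dpx[ok] * d2y[ok] - dpy[ok] * d2x[ok]) / den[ok]
      ss <- (dpx[ok] * d1y - dpy[ok] * d1x) / den[ok]
      if (any(tt > tol & tt < 1 - tol & ss > tol & ss < 1 - tol)) return(FALSE)
    }
    if (any(!ok)) {
      ## parallel pair: overlap only if collinear with overlapping ranges
      par <- js[!ok]
      coll <- par[abs((a[par, 1L] - a[i, 1L]) * d1y -
                      (a[par, 2L] - a[i, 2L]) * d1x) <= tol]
      if (length(coll)) {
        l2 <- d1x^2 + d1y^2
        if (l2 > tol) {
          t3 <- ((a[coll, 1L] - a[i, 1L]) * d1x + (a[coll, 2L] - a[i, 2L]) * d1y) / l2
          t4 <- ((b[coll, 1L] - a[i, 1L]) * d1x + (b[coll, 2L] - a[i, 2L]) * d1y) / l2
          lo <- pmin(t3, t4); hi <- pmax(t3, t4)
          if (any(hi > tol & lo < 1 - tol)) return(FALSE)
        }
      }
    }
  }
  TRUE
}

#' Construct a closed planar contour
#'
#' A contour is an ordered list of >= 3 in-plane 2D points (mm) lying in one
#' \code{\link{image_plane}}; closure is implicit (the first point is not
#' repeated).  The polygon must be simple; orientation is normalised to
#' counter-clockwise in the \code{(u, v)} frame on construction, since
#' delineation tools emit either winding.
#'
#' @param plane an \code{image_plane}.
#' @param points numeric n x 2 matrix of in-plane coordinates (mm), n >= 3.
#' @param surface \code{"endocardium"} or \code{"epicardium"}.
#' @param phase \code{"ED"} (end-diastole) or \code{"ES"} (end-systole).
#' @param slice_index integer, 0 = most basal SAX slice; \code{NULL} for a
#'   LAX contour.
#' @return an object of class \code{planar_contour}.
#' @export
planar_contour <- function(plane, points, surface = "endocardium",
                           phase = "ED", slice_index = NULL) {
  if (!inherits(plane, "image_plane")) stop("planar_contour: plane must be an image_plane")
  points <- matrix(as.numeric(points), ncol = 2L)
  ## drop consecutive duplicates (incl. wrap-around)
  if (nrow(points) > 1L) {
    keep <- c(TRUE, rowSums(abs(diff(points))) > 1e-9)
    points <- points[keep, , drop = FALSE]
    n <- nrow(points)
    if (n > 1L && sum(abs(points[n, ] - points[1L, ])) <= 1e-9)
      points <- points[-n, , drop = FALSE]
  }
  if (nrow(points) < 3L)
    stop("invalid-geometry: degenerate polygon (<3 distinct points)")
  sa <- shoelace_signed_area(points)
  if (abs(sa) < 1e-9)
    stop("invalid-geometry: polygon has zero area")
  if (!polygon_is_simple(points))
    stop("invalid-geometry: polygon is self-intersecting (not repaired)")
  if (sa < 0) points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
  surface <- match.arg(surface, c("endocardium", "epicardium"))
  phase <- match.arg(phase, c("ED", "ES"))
  structure(
    list(plane = plane, points = points, surface = surface, phase = phase,
         slice_index = if (is.null(slice_index)) NULL else as.integer(slice_index)),
    class = "planar_contour"
  )
}

#' @export
print.planar_contour <- function(x, ...) {
  cat("planar_contour: ", nrow(x$points), " vertices, ", x$surface, ", ",
      x$phase,
      if (is.null(x$slice_index)) " (LAX)" else sprintf(" (SAX slice %d)", x$slice_index),
      ", area ", sprintf("%.2f", polygon_area(x)), " mm^2\n", sep = "")
  invisible(x)
}

#' 3D vertex coordinates of a contour
#'
#' @param contour a \code{planar_contour}.
#' @return n x 3 matrix of vertex positions in patient coordinates (mm).
#' @export
contour_points_3d <- function(contour) {
  plane_to_world(contour$plane, contour$points)
}

#' Enclosed area of a planar contour
#'
#' Absolute shoelace area of the polygon in its in-plane frame.
#'
#' @param contour a \code{planar_contour}.
#' @return area in mm^2 (strictly positive).
#' @export
polygon_area <- function(contour) {
  stopifnot(inherits(contour, "planar_contour"))
  abs(shoelace_signed_area(contour$points))
}

#' Area-weighted centroid of a planar contour
#'
#' @param contour a \code{planar_contour}.
#' @return length-3 numeric: centroid in 3D patient coordinates (mm).
#' @export
polygon_centroid <- function(contour) {
  stopifnot(inherits(contour, "planar_contour"))
  p <- contour$points
  n <- nrow(p)
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  drop(plane_to_world(contour$plane, c(cx, cy)))
}

#' A 3D line segment
#'
#' @param a,b length-3 numeric endpoints (mm).
#' @return object of class \code{line_segment3} with fields \code{a},
#'   \code{b}, \code{length}.
#' @export
line_segment3 <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 3L, length(b) == 3L)
  structure(list(a = a, b = b, length = sqrt(sum((b - a)^2))),
            class = "line_segment3")
}

#' Intersection of a contour boundary with a cutting plane
#'
#' Finds where the polygon's edges cross the cutting plane, snapping
#' vertex-on-plane cases (within \code{tol} mm) to a single point, and
#' returns the crossings sorted along the line in which the two planes
#' intersect.  A simple closed polygon in general position yields an even
#' number of points.
#'
#' @param contour a \code{planar_contour}.
#' @param cutting an \code{image_plane} transverse to the contour's plane
#'   (angular tolerance 1e-6 rad).
#' @param tol merge tolerance in mm for coincident crossings (default 1e-6).
#' @return m x 3 matrix of intersection points (possibly 0 rows), sorted
#'   along the intersection line.
#' @export
plane_contour_intersection <- function(contour, cutting, tol = 1e-6) {
  stopifnot(inherits(contour, "planar_contour"), inherits(cutting, "image_plane"))
  ldir <- cross3(contour$plane$normal, cutting$normal)
  if (sqrt(sum(ldir^2)) < 1e-6)
    stop("no-intersection: cutting plane is parallel to the contour's plane")
  ldir <- unit3(ldir)
  p3 <- contour_points_3d(contour)
  d <- plane_signed_distance(cutting, p3)
  d[abs(d) < tol] <- 0      # snap vertices lying on the plane
  n <- nrow(p3)
  nxt <- c(2:n, 1L)
  on_plane <- d == 0
  crossing <- !on_plane & d * d[nxt] < 0
  pts <- p3[on_plane, , drop = FALSE]   # vertex on plane: counted once
  if (any(crossing)) {
    i <- which(crossing); j <- nxt[i]
    t <- d[i] / (d[i] - d[j])
    pts <- rbind(pts, p3[i, , drop = FALSE] + t * (p3[j, , drop = FALSE] - p3[i, , drop = FALSE]))
  }
  if (nrow(pts) == 0L) return(pts)
  s <- as.numeric(pts %*% ldir)
  o <- order(s)
  pts <- pts[o, , drop = FALSE]
  s <- s[o]
  keep <- c(TRUE, diff(s) > tol)        # merge duplicates within tol
  pts[keep, , drop = FALSE]
}

#' Outermost chord of a contour cut by a plane
#'
#' The segment joining the two outermost intersection points along the
#' cutting line: the LV "diameter" measured on a LAX contour at a SAX
#' plane.  With more than two crossings (e.g. papillary indentations) the
#' outermost pair is chosen.
#'
#' @inheritParams plane_contour_intersection
#' @return a \code{line_segment3}.
#' @export
chord_through <- function(contour, cutting, tol = 1e-6) {
  pts <- plane_contour_intersection(contour, cutting, tol)
  if (nrow(pts) < 2L)
    stop("missing-chord: cutting plane intersects the contour in fewer than 2 points")
  line_segment3(pts[1L, ], pts[nrow(pts), ])
}

#' Clip a contour to the slab between two planes
#'
#' Returns the sub-polygon of \code{contour} lying between the two cutting
#' planes, closed by the chord segments on each plane (Sutherland-Hodgman
#' clipping against each half-space).  Applied to a LAX contour and two
#' adjacent SAX planes this yields the chunk's LAX cross-sectional area.
#'
#' @param contour a \code{planar_contour} transverse to both planes.
#' @param upper,lower distinct \code{image_plane}s; the retained region is
#'   the side of each plane containing the other plane's origin.
#' @return a \code{planar_contour} in the same plane as the input.
#' @export
clip_contour_between_planes <- function(contour, upper, lower) {
  pts2 <- clip_points_between_planes(contour, upper, lower)
  planar_contour(contour$plane, pts2, surface = contour$surface,
                 phase = contour$phase, slice_index = contour$slice_index)
}

## raw clipped vertex ring; for a non-convex contour whose slab section is
## disconnected, the components come back joined by zero-width bridges
## along the cutting lines — harmless for area, rejected by the simple-
## polygon check in clip_contour_between_planes
clip_points_between_planes <- function(contour, upper, lower) {
  stopifnot(inherits(contour, "planar_contour"))
  pts2 <- clip_halfplane(contour$points, contour$plane, upper, lower$origin)
  if (is.null(pts2) || nrow(pts2) < 3L)
    stop("empty-region: clip region lies outside the contour")
  pts2 <- clip_halfplane(pts2, contour$plane, lower, upper$origin)
  if (is.null(pts2) || nrow(pts2) < 3L)
    stop("empty-region: clip region lies outside the contour")
  if (abs(shoelace_signed_area(pts2)) < 1e-9)
    stop("empty-region: clipped polygon has zero area")
  pts2
}

## enclosed area (mm^2) of the slab section, robust to disconnected
## sections (bridge edges cancel in the shoelace sum)
clip_area_between_planes <- function(contour, upper, lower) {
  abs(shoelace_signed_area(clip_points_between_planes(contour, upper, lower)))
}

## Sutherland-Hodgman clip of a 2D in-plane polygon against the half-space
## of `cut` containing `ref_point` (a 3D point).  Signed distance is affine
## in the in-plane coordinates, so clipping happens directly in 2D.
clip_halfplane <- function(pts2, plane, cut, ref_point) {
  sref <- plane_signed_distance(cut, matrix(ref_point, ncol = 3L))
  sgn <- if (sref >= 0) 1 else -1
  p3 <- plane_to_world(plane, pts2)
  d <- sgn * plane_signed_distance(cut, p3)
  n <- nrow(pts2)
  nxt <- c(2:n, 1L)
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(n)) {
    j <- nxt[i]
    di <- d[i]; dj <- d[j]
    if (di >= -1e-12) out <- rbind(out, pts2[i, ])
    if ((di > 1e-12 && dj < -1e-12) || (di < -1e-12 && dj > 1e-12)) {
      t <- di / (di - dj)
      out <- rbind(out, pts2[i, ] + t * (pts2[j, ] - pts2[i, ]))
    }
  }
  out
}

#' Acute angle between a line and a plane
#'
#' @param line a \code{line_segment3} with nonzero length.
#' @param plane an \code{image_plane}.
#' @return angle in radians in \[0, pi/2\]: 0 when the line lies in the
#'   plane, pi/2 when it is along the normal.
#' @export
angle_plane_to_line <- function(line, plane) {
  stopifnot(inherits(line, "line_segment3"), inherits(plane, "image_plane"))
  if (line$length < 1e-12)
    stop("invalid-geometry: zero-length line")
  dirv <- (line$b - line$a) / line$length
  s <- abs(sum(dirv * plane$normal))
  asin(min(1, s))
}

#' Apply a rigid motion to a contour
#'
#' Rotates (about the origin of patient space) then translates the
#' contour's plane; in-plane coordinates are unchanged, so areas and all
#' in-plane measurements are preserved exactly.
#'
#' @param contour a \code{planar_contour}.
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @param translation length-3 numeric (mm, default zero).
#' @return the transformed \code{planar_contour}.
#' @export
transform_contour <- function(contour, rotation = diag(3), translation = c(0, 0, 0)) {
  pl <- contour$plane
  newpl <- image_plane(as.numeric(rotation %*% pl$origin) + translation,
                       as.numeric(rotation %*% pl$axis_u),
                       as.numeric(rotation %*% pl$axis_v))
  planar_contour(newpl, contour$points, surface = contour$surface,
                 phase = contour$phase, slice_index = contour$slice_index)
}
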