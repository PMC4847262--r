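## Volume estimators: modified Simpson disc summation, the trapezoidal
## SAX+LAX fusion model (closed form and numeric-integral reference form),
## and the classical few-slice geometric models.  Internal computations are
## in mm^3; every exported estimator reports ml.

#' Construct a volume estimate
#'
#' @param per_chunk numeric vector of per-chunk (or per-disc) volumes in ml,
#'   named by chunk/slice index.
#' @param method method label.
#' @param n_slices_used number of SAX slices that entered the estimate.
#' @return object of class \code{volume_estimate} with fields \code{total}
#'   (ml), \code{per_chunk}, \code{method}, \code{n_slices_used}.
#' @export
volume_estimate <- function(per_chunk, method, n_slices_used) {
  per_chunk <- unlist(per_chunk)
  if (any(per_chunk < 0)) stop("volume_estimate: negative per-chunk volume")
  structure(
    list(total = sum(per_chunk), per_chunk = per_chunk,
         method = method, n_slices_used = as.integer(n_slices_used)),
    class = "volume_estimate"
  )
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("volume_estimate [%s]: %.2f ml from %d SAX slice(s) (%d parts)\n",
              x$method, x$total, x$n_slices_used, length(x$per_chunk)))
  invisible(x)
}

#' Modified Simpson (disc summation) volume
#'
#' Each SAX slice contributes a disc of its contour area times the
#' per-slice extent t + l.  For stacks whose planes are not uniformly
#' spaced (e.g. a retained subset), the extent of a slice is the distance
#' to the next retained plane towards the apex; the most apical slice uses
#' the mean of the other extents.  A single-slice stack requires
#' \code{slice_thickness}/\code{gap} metadata.
#'
#' @param stack a \code{contour_stack}.
#' @return a \code{volume_estimate} (ml).
#' @export
msimp_volume <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  stack <- sort_stack_axially(stack)
  N <- length(stack$sax)
  areas <- vapply(stack$sax, polygon_area, numeric(1))
  if (N == 1L) {
    if (is.null(stack$slice_thickness))
      stop("configuration: single-slice stack needs slice_thickness (+ gap) metadata")
    ext <- stack$slice_thickness + stack$gap
  } else {
    pos <- sax_positions(stack)
    ext <- abs(diff(pos))
    if (any(ext < 1e-9))
      stop("configuration: coincident SAX planes; per-slice extent undefined")
    ext <- c(ext, mean(ext))
  }
  v <- areas * ext / 1000
  names(v) <- vapply(stack$sax, `[[`, integer(1), "slice_index")
  volume_estimate(v, method = "msimp", n_slices_used = N)
}

#' Trapezoidal volume of a single LV chunk
#'
#' Interior and basal-virtual chunks: the chunk's LAX cross-sectional
#' area divided by the summed LAX diameters times the summed SAX areas.
#' The apical chunk is the specialisation with zero lower diameter and
#' area (triangle-closed apex): LAX area times upper SAX area over twice
#' the upper diameter.
#'
#' @param chunk an \code{lv_chunk}.
#' @param oblique_correction deflate the LAX area by cos(obliquity) before
#'   use (default \code{TRUE}; no-op at obliquity 0).
#' @return chunk volume in ml.
#' @export
trapezoidal_chunk_volume <- function(chunk, oblique_correction = TRUE) {
  stopifnot(inherits(chunk, "lv_chunk"))
  if (oblique_correction && chunk$obliquity > 0) chunk <- correct_lax_area(chunk)
  if (chunk$kind == "apical") {
    if (chunk$d_upper <= 0)
      stop("degenerate-chunk: apical chunk with zero upper diameter")
    v <- chunk$lax_area * chunk$upper_area / (2 * chunk$d_upper)
  } else {
    den <- chunk$d_upper + chunk$d_lower
    if (den <= 0)
      stop("degenerate-chunk: zero summed diameters")
    v <- chunk$lax_area * (chunk$upper_area + chunk$lower_area) / den
  }
  v / 1000
}

#' Trapezoidal SAX+LAX fusion volume
#'
#' Decomposes the stack into chunks and sums the per-chunk trapezoidal
#' volumes.  The virtual chunk above the most basal plane is excluded by
#' default (no reference standard exists for it).
#'
#' @param stack a \code{contour_stack} with >= 2 SAX contours and one LAX
#'   contour.
#' @param include_basal_virtual include the mirrored basal virtual chunk.
#' @param oblique_correction apply the cos(obliquity) LAX-area correction.
#' @return a \code{volume_estimate} (ml) with per-chunk breakdown.
#' @export
trapezoidal_volume <- function(stack, include_basal_virtual = FALSE,
                               oblique_correction = TRUE) {
  chunks <- build_chunks(stack, include_basal_virtual = include_basal_virtual)
  v <- vapply(chunks, trapezoidal_chunk_volume, numeric(1),
              oblique_correction = oblique_correction)
  names(v) <- vapply(chunks, `[[`, numeric(1), "index")
  volume_estimate(v, method = "trapezoidal", n_slices_used = length(stack$sax))
}

#' Trapezoidal volume by numeric wedge integration
#'
#' Reference form of the fusion model: each chunk's volume is obtained by
#' rotating its equivalent trapezoid about the chunk axis and integrating
#' the wedge volumes over theta in \[0, pi\] (a full revolution, since each
#' diameter spans both sides of the axis) with the trapezoid rule.  The
#' diameters at angle theta are chords of the SAX polygons through the
#' chunk axis; theta is measured from the LAX plane.  The closed-form
#' estimator approximates this integral by the mean SAX area; agreement
#' between the two validates that approximation.
#'
#' @inheritParams trapezoidal_volume
#' @param n_theta number of trapezoid-rule panels over \[0, pi\] (>= 8).
#' @return a \code{volume_estimate} (ml).
#' @export
trapezoidal_integral_volume <- function(stack, n_theta = 360,
                                        include_basal_virtual = FALSE,
                                        oblique_correction = TRUE) {
  if (n_theta < 8) stop("resolution: n_theta must be at least 8")
  chunks <- build_chunks(stack, include_basal_virtual = include_basal_virtual)
  theta <- seq(0, pi, length.out = n_theta + 1L)
  v <- vapply(chunks, function(ch) {
    if (oblique_correction && ch$obliquity > 0) ch <- correct_lax_area(ch)
    d_up <- sax_chords_at_angles(ch$upper_contour, ch$lax_plane, theta)
    d_lo <- if (is.null(ch$lower_contour)) rep(0, length(theta))
            else sax_chords_at_angles(ch$lower_contour, ch$lax_plane, theta)
    den <- ch$d_upper + ch$d_lower
    if (den <= 0) stop("degenerate-chunk: zero summed diameters")
    integrand <- ((d_up + d_lo) / 2)^2
    integral <- sum((integrand[-1L] + integrand[-length(integrand)]) / 2) * (pi / n_theta)
    0.5 * ch$lax_area / den * integral / 1000
  }, numeric(1))
  names(v) <- vapply(chunks, `[[`, numeric(1), "index")
  volume_estimate(v, method = "trapezoidal-integral",
                  n_slices_used = length(stack$sax))
}

## chord lengths of a SAX contour through its centroid, at angles theta
## measured from the LAX-plane intersection direction
sax_chords_at_angles <- function(contour, lax_plane, theta) {
  pl <- contour$plane
  ldir <- cross3(pl$normal, lax_plane$normal)
  nl <- sqrt(sum(ldir^2))
  if (nl < 1e-9)
    stop("degenerate-chunk: LAX plane parallel to SAX plane")
  ldir <- ldir / nl
  perp <- cross3(pl$normal, ldir)
  cent2 <- world_to_plane(pl, matrix(polygon_centroid(contour), ncol = 3L))
  l2 <- c(sum(ldir * pl$axis_u), sum(ldir * pl$axis_v))
  p2 <- c(sum(perp * pl$axis_u), sum(perp * pl$axis_v))
  vapply(theta, function(th) {
    dir2 <- l2 * cos(th) + p2 * sin(th)
    polygon_line_chord(contour$points, cent2, dir2)
  }, numeric(1))
}

## outermost extent of a 2D polygon along the infinite line p0 + s*dir
polygon_line_chord <- function(pts2, p0, dir2) {
  n <- nrow(pts2)
  a <- pts2
  b <- pts2[c(2:n, 1L), , drop = FALSE]
  ex <- b[, 1L] - a[, 1L]; ey <- b[, 2L] - a[, 2L]
  den <- dir2[1L] * ey - dir2[2L] * ex
  dpx <- a[, 1L] - p0[1L]; dpy <- a[, 2L] - p0[2L]
  ok <- abs(den) > 1e-12
  tt <- (dpx * dir2[2L] - dpy * dir2[1L]) / den   # param along the edge
  ss <- (dpx * ey - dpy * ex) / den               # param along the line
  hit <- ok & tt >= 0 & tt < 1
  if (sum(hit) < 2L) return(0)
  max(ss[hit]) - min(ss[hit])
}

#' Classical few-slice geometric volume models
#'
#' Standard echocardiography-literature formulas, applied to MR-derived
#' measurements.  Lengths in mm, areas in mm^2; volumes returned in ml.
#' \describe{
#'   \item{single-plane}{area-length ellipsoid from one LAX view:
#'     V = 8 A^2 / (3 pi L).}
#'   \item{biplane}{area-length from two orthogonal LAX views:
#'     V = (8 / (3 pi)) A1 A2 / L.}
#'   \item{teichholz}{from the mid-cavity SAX diameter D (internally in
#'     cm): V = 7.0 D^3 / (2.4 + D).}
#'   \item{hemisphere-cylinder}{"bullet" model from one mid SAX area and
#'     the long-axis length: V = (5/6) A L.}
#' }
#'
#' @param model one of \code{"single-plane"}, \code{"biplane"},
#'   \code{"teichholz"}, \code{"hemisphere-cylinder"}.
#' @param A LAX area (single-plane) or mid SAX area (hemisphere-cylinder),
#'   mm^2.
#' @param A1,A2 two orthogonal LAX areas (biplane), mm^2.
#' @param L long-axis length, mm.
#' @param D mid-cavity SAX diameter (teichholz), mm.
#' @return volume in ml.
#' @examples
#' classical_volume("teichholz", D = 40)                 # 70 ml
#' classical_volume("hemisphere-cylinder", A = pi * 20^2, L = 90)
#' @export
classical_volume <- function(model, A = NULL, A1 = NULL, A2 = NULL,
                             L = NULL, D = NULL) {
  model <- match.arg(model, c("single-plane", "biplane", "teichholz",
                              "hemisphere-cylinder"))
  need <- function(x, nm) {
    if (is.null(x)) stop(sprintf("classical_volume: model '%s' needs %s", model, nm))
    if (x <= 0) stop(sprintf("classical_volume: %s must be positive", nm))
    x
  }
  mm3 <- switch(model,
    "single-plane" = 8 * need(A, "A")^2 / (3 * pi * need(L, "L")),
    "biplane" = 8 / (3 * pi) * need(A1, "A1") * need(A2, "A2") / need(L, "L"),
    "teichholz" = {
      d_cm <- need(D, "D") / 10
      return(7.0 * d_cm^3 / (2.4 + d_cm))   # formula is already in ml
    },
    "hemisphere-cylinder" = 5 / 6 * need(A, "A") * need(L, "L"))
  mm3 / 1000
}
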