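## Chunk decomposition: convert one SAX contour stack plus one LAX contour
## into the ordered list of inter-slice LV chunks consumed by the volume
## models, including the oblique-LAX cosine area correction.

#' Bundle SAX contours and a LAX contour into a stack
#'
#' @param sax list of \code{planar_contour}s ordered base to apex; their
#'   planes must be mutually parallel (within 1e-6 rad) and all contours
#'   must share one surface and phase.  \code{slice_index} is assigned
#'   0..N-1 (0 = most basal) when absent.
#' @param lax a single LAX \code{planar_contour}, or \code{NULL} for
#'   SAX-only stacks (sufficient for the modified Simpson method).
#' @param slice_thickness,gap acquisition slice thickness t and inter-slice
#'   gap l (mm); optional when the per-slice extent is derivable from the
#'   plane positions (any stack with >= 2 slices).
#' @return an object of class \code{contour_stack}.
#' @export
contour_stack <- function(sax, lax = NULL, slice_thickness = NULL, gap = 0) {
  if (inherits(sax, "planar_contour")) sax <- list(sax)
  if (length(sax) < 1L) stop("contour_stack: at least one SAX contour required")
  if (!all(vapply(sax, inherits, logical(1), "planar_contour")))
    stop("contour_stack: sax must be a list of planar_contour objects")
  n0 <- sax[[1L]]$plane$normal
  for (k in seq_along(sax)) {
    s <- abs(sum(sax[[k]]$plane$normal * n0))
    if (acos(min(1, s)) > 1e-6)
      stop(sprintf("contour_stack: SAX plane %d is not parallel to the first (within 1e-6 rad)", k))
  }
  surf <- unique(vapply(sax, `[[`, character(1), "surface"))
  ph <- unique(vapply(sax, `[[`, character(1), "phase"))
  if (length(surf) != 1L || length(ph) != 1L)
    stop("contour_stack: all SAX contours must share one surface and phase")
  idx <- vapply(sax, function(s) if (is.null(s$slice_index)) NA_integer_ else s$slice_index, integer(1))
  if (all(is.na(idx))) {
    for (k in seq_along(sax)) sax[[k]]$slice_index <- k - 1L
  } else if (anyNA(idx) || any(diff(idx) <= 0)) {
    stop("contour_stack: SAX slice_index must be strictly increasing base to apex")
  }
  if (!is.null(lax) && !inherits(lax, "planar_contour"))
    stop("contour_stack: lax must be a planar_contour or NULL")
  structure(
    list(sax = sax, lax = lax,
         slice_thickness = slice_thickness, gap = gap,
         surface = surf, phase = ph),
    class = "contour_stack"
  )
}

#' @export
print.contour_stack <- function(x, ...) {
  cat("contour_stack: ", length(x$sax), " SAX slice(s)",
      if (!is.null(x$lax)) " + 1 LAX contour", ", ", x$surface, ", ", x$phase,
      "\n", sep = "")
  if (!is.null(x$slice_thickness))
    cat("  slice thickness ", x$slice_thickness, " mm, gap ", x$gap, " mm\n", sep = "")
  invisible(x)
}

## unit long-axis direction of the stack, oriented base -> apex
stack_axis <- function(stack) {
  n <- stack$sax[[1L]]$plane$normal
  N <- length(stack$sax)
  if (N >= 2L) {
    span <- stack$sax[[N]]$plane$origin - stack$sax[[1L]]$plane$origin
    if (sum(span * n) < 0) n <- -n
  }
  n
}

## axial coordinate (mm) of each SAX plane along the base->apex direction
sax_positions <- function(stack) {
  ax <- stack_axis(stack)
  vapply(stack$sax, function(s) sum(s$plane$origin * ax), numeric(1))
}

## reorder SAX slices by axial position (base first); motion simulation can
## perturb the nominal ordering, and the inter-slice slabs only partition
## the LV when slices are chunked in positional order
sort_stack_axially <- function(stack) {
  pos <- sax_positions(stack)
  o <- order(pos)
  stack$sax <- stack$sax[o]
  stack
}

#' Decompose a contour stack into LV chunks
#'
#' Splits the LV into the region between each adjacent SAX plane pair
#' (interior chunks), the region below the most apical plane (apical
#' chunk, triangle-closed at the apex), and optionally a virtual chunk
#' above the most basal plane with mirrored fields.  Each chunk carries
#' the clipped LAX cross-sectional area, the two LAX-derived diameters,
#' the SAX contour areas, and the obliquity angle between the chunk's
#' centroid axis and the LAX plane.
#'
#' Slices are processed in order of axial position (base to apex);
#' the diameters are always measured on the LAX contour, which delineates
#' the LV more reliably than SAX slices near the apex.
#'
#' @param stack a \code{contour_stack} with >= 2 SAX contours and a LAX
#'   contour transverse to the SAX planes.
#' @param include_basal_virtual add the mirrored virtual chunk above the
#'   most basal plane (default \code{FALSE}; its volume has no reference
#'   standard and is excluded from totals unless requested).
#' @return list of \code{lv_chunk} records ordered base to apex; indices:
#'   0 = basal virtual (if present), 1..N-1 interior, N apical.
#' @export
build_chunks <- function(stack, include_basal_virtual = FALSE) {
  stopifnot(inherits(stack, "contour_stack"))
  if (length(stack$sax) < 2L)
    stop("build_chunks: at least 2 SAX contours are required")
  if (is.null(stack$lax))
    stop("build_chunks: stack has no LAX contour")
  stack <- sort_stack_axially(stack)
  sax <- stack$sax
  lax <- stack$lax
  N <- length(sax)
  ax <- stack_axis(stack)

  ## LAX chord and SAX area/centroid at every SAX plane
  chords <- vector("list", N)
  for (k in seq_len(N)) {
    chords[[k]] <- tryCatch(
      chord_through(lax, sax[[k]]$plane),
      error = function(e) stop(sprintf(
        "decomposition: no LAX chord at SAX slice %s (%s)",
        sax[[k]]$slice_index, conditionMessage(e)))
    )
  }
  areas <- vapply(sax, polygon_area, numeric(1))
  cents <- t(vapply(sax, polygon_centroid, numeric(3)))

  chunks <- list()

  if (include_basal_virtual) {
    bc <- basal_virtual_chunk(stack, chords[[1L]], areas[1L], cents[1L, ], cents[2L, ])
    if (!is.null(bc)) chunks[[length(chunks) + 1L]] <- bc
  }

  for (k in seq_len(N - 1L)) {
    ## an empty slab (planes brought to near-coincidence, e.g. by motion
    ## simulation) encloses no volume: keep a zero-area chunk
    a_lax <- tryCatch(
      clip_area_between_planes(lax, sax[[k]]$plane, sax[[k + 1L]]$plane),
      error = function(e) {
        if (grepl("empty-region", conditionMessage(e))) 0 else stop(e)
      })
    phi <- angle_plane_to_line(line_segment3(cents[k, ], cents[k + 1L, ]), lax$plane)
    chunks[[length(chunks) + 1L]] <- new_chunk(
      index = k, kind = "interior",
      upper_area = areas[k], lower_area = areas[k + 1L], lax_area = a_lax,
      d_upper = chords[[k]]$length, d_lower = chords[[k + 1L]]$length,
      obliquity = phi,
      upper_contour = sax[[k]], lower_contour = sax[[k + 1L]], lax_plane = lax$plane)
  }

  ap <- apical_chunk(stack, chords[[N]], areas[N], cents[N, ], cents[N - 1L, ])
  if (is.null(ap)) {
    warning("apical chunk omitted: LAX contour does not extend below the most apical SAX plane")
  } else {
    chunks[[length(chunks) + 1L]] <- ap
  }

  chunks
}

new_chunk <- function(index, kind, upper_area, lower_area, lax_area,
                      d_upper, d_lower, obliquity,
                      upper_contour = NULL, lower_contour = NULL, lax_plane = NULL) {
  stopifnot(upper_area >= 0, lower_area >= 0, lax_area >= 0,
            d_upper >= 0, d_lower >= 0)
  structure(
    list(index = index, kind = kind,
         upper_area = upper_area, lower_area = lower_area, lax_area = lax_area,
         d_upper = d_upper, d_lower = d_lower, obliquity = obliquity,
         upper_contour = upper_contour, lower_contour = lower_contour,
         lax_plane = lax_plane),
    class = "lv_chunk"
  )
}

#' @export
print.lv_chunk <- function(x, ...) {
  cat(sprintf(
    "lv_chunk %d (%s): A_up %.1f, A_low %.1f, A_lax %.1f mm^2; d_up %.1f, d_low %.1f mm; phi %.2f deg\n",
    x$index, x$kind, x$upper_area, x$lower_area, x$lax_area,
    x$d_upper, x$d_lower, x$obliquity * 180 / pi))
  invisible(x)
}

## clip a contour to the half-space of `cut` away from `ref_point`
clip_contour_beyond_plane <- function(contour, cut, ref_point) {
  sref <- plane_signed_distance(cut, matrix(ref_point, ncol = 3L))
  sgn <- if (sref >= 0) 1 else -1
  far_ref <- cut$origin - sgn * cut$normal   # just beyond the plane, far side
  pts2 <- clip_halfplane(contour$points, contour$plane, cut, far_ref)
  if (is.null(pts2) || nrow(pts2) < 3L) return(NULL)
  if (abs(shoelace_signed_area(pts2)) < 1e-9) return(NULL)
  planar_contour(contour$plane, pts2, surface = contour$surface,
                 phase = contour$phase, slice_index = contour$slice_index)
}

apical_chunk <- function(stack, chord_last, area_last, cent_last, cent_prev) {
  lax <- stack$lax
  N <- length(stack$sax)
  last_plane <- stack$sax[[N]]$plane
  clipped <- clip_contour_beyond_plane(lax, last_plane, cent_prev)
  if (is.null(clipped)) return(NULL)
  ## apex point: clipped-LAX vertex farthest from the most apical plane
  p3 <- contour_points_3d(clipped)
  d <- abs(plane_signed_distance(last_plane, p3))
  apex <- p3[which.max(d), ]
  phi <- angle_plane_to_line(line_segment3(cent_last, apex), lax$plane)
  new_chunk(index = N, kind = "apical",
            upper_area = area_last, lower_area = 0,
            lax_area = polygon_area(clipped),
            d_upper = chord_last$length, d_lower = 0, obliquity = phi,
            upper_contour = stack$sax[[N]], lower_contour = NULL,
            lax_plane = lax$plane)
}

basal_virtual_chunk <- function(stack, chord_first, area_first, cent_first, cent_second) {
  lax <- stack$lax
  first_plane <- stack$sax[[1L]]$plane
  clipped <- clip_contour_beyond_plane(lax, first_plane, cent_second)
  if (is.null(clipped)) {
    warning("basal virtual chunk omitted: LAX contour does not extend above the most basal SAX plane")
    return(NULL)
  }
  phi <- angle_plane_to_line(line_segment3(cent_first, cent_second), lax$plane)
  new_chunk(index = 0L, kind = "basal_virtual",
            upper_area = area_first, lower_area = area_first,
            lax_area = polygon_area(clipped),
            d_upper = chord_first$length, d_lower = chord_first$length,
            obliquity = phi,
            upper_contour = stack$sax[[1L]], lower_contour = stack$sax[[1L]],
            lax_plane = lax$plane)
}

#' Correct a chunk's LAX area for an oblique LAX plane
#'
#' An oblique LAX plane (one not containing the chunk's centroid axis)
#' cuts the chunk in a larger apparent cross-section; the area is deflated
#' by the cosine of the obliquity angle.
#'
#' @param chunk an \code{lv_chunk} with obliquity in \[0, pi/2).
#' @return the chunk with \code{lax_area} replaced by
#'   \code{lax_area * cos(obliquity)}.
#' @export
correct_lax_area <- function(chunk) {
  stopifnot(inherits(chunk, "lv_chunk"))
  if (chunk$obliquity >= pi / 2)
    stop("invalid-obliquity: obliquity angle must be below pi/2")
  chunk$lax_area <- chunk$lax_area * cos(chunk$obliquity)
  chunk
}

#' Drop SAX slices whose plane misses the LAX contour
#'
#' Quality-control step for misregistered acquisitions: a SAX slice whose
#' plane no longer crosses the LAX contour (e.g. displaced beyond the
#' apex by breath-hold motion) carries no usable fusion information and
#' is excluded, mirroring the clinical exclusion of motion-corrupted
#' slices.
#'
#' @param stack a \code{contour_stack} with a LAX contour.
#' @return the stack with chordless SAX slices removed (warning names
#'   them); errors if fewer than 2 slices remain.
#' @export
drop_chordless_slices <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  if (is.null(stack$lax)) return(stack)
  ok <- vapply(stack$sax, function(s) {
    tryCatch({ chord_through(stack$lax, s$plane); TRUE },
             error = function(e) FALSE)
  }, logical(1))
  if (!all(ok)) {
    dropped <- vapply(stack$sax[!ok], `[[`, integer(1), "slice_index")
    warning("dropped SAX slice(s) without a LAX chord: ",
            paste(dropped, collapse = ", "))
    stack$sax <- stack$sax[ok]
  }
  if (length(stack$sax) < 2L)
    stop("decomposition: fewer than 2 SAX slices cross the LAX contour")
  stack
}

#' Retain a uniformly covering subset of SAX slices
#'
#' Keeps the most basal and most apical slices plus n-2 slices whose
#' axial positions most uniformly cover the base-apex distance (nearest
#' available slice to each ideal position; ties resolved to the more
#' basal slice).
#'
#' @param stack a \code{contour_stack} with N SAX slices.
#' @param n number of slices to retain, 2 <= n <= N.
#' @return a \code{contour_stack} with n SAX slices; per-slice extents are
#'   recomputed downstream from the retained plane positions.
#' @export
select_slice_subset <- function(stack, n) {
  stopifnot(inherits(stack, "contour_stack"))
  N <- length(stack$sax)
  if (n > N || n < 2L) stop("invalid-count: need 2 <= n <= number of slices")
  if (n == N) return(stack)
  pos <- sax_positions(stack)
  ideal <- pos[1L] + (pos[N] - pos[1L]) * (seq_len(n) - 1L) / (n - 1L)
  chosen <- integer(0)
  for (tgt in ideal) {
    avail <- setdiff(seq_len(N), chosen)
    dist <- abs(pos[avail] - tgt)
    ## ties to the more basal slice: order() is stable and avail is sorted
    chosen <- c(chosen, avail[which.min(round(dist, 9))])
  }
  chosen <- sort(chosen)
  stack$sax <- stack$sax[chosen]
  stack
}
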