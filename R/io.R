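## Contour interchange: a small versioned JSON dialect carrying, per
## (phase, surface) stack, each contour's image plane (origin + in-plane
## frame) and its 2D in-plane points in mm.  Storing in-plane coordinates
## plus the plane frame makes plane membership true by construction.
## The schema is documented in inst/extdata/contour-schema.json.

CONTOUR_SCHEMA_VERSION <- "1.0"

#' Write contour stacks to a JSON contour file
#'
#' @param stacks a \code{contour_stack} or a named list of them (names
#'   like \code{"ED.endocardium"} are informative only; phase/surface are
#'   taken from the stacks themselves).
#' @param path output file path.
#' @param subject_id identifier stored in the file.
#' @return \code{path}, invisibly.
#' @export
write_contours <- function(stacks, path, subject_id = "unknown") {
  if (inherits(stacks, "contour_stack")) stacks <- list(stacks)
  ser_plane <- function(p) list(origin = p$origin, axis_u = p$axis_u, axis_v = p$axis_v)
  ser_contour <- function(ct) {
    rec <- list(view = if (is.null(ct$slice_index)) "LAX" else "SAX",
                plane = ser_plane(ct$plane),
                points = lapply(seq_len(nrow(ct$points)), function(r) ct$points[r, ]))
    if (!is.null(ct$slice_index)) rec$slice_index <- ct$slice_index
    rec
  }
  doc <- list(
    schema_version = CONTOUR_SCHEMA_VERSION,
    subject_id = subject_id,
    units = "mm",
    stacks = lapply(unname(stacks), function(st) {
      rec <- list(phase = st$phase, surface = st$surface,
                  slice_thickness_mm = st$slice_thickness, gap_mm = st$gap,
                  contours = c(lapply(st$sax, ser_contour),
                               if (!is.null(st$lax)) list(ser_contour(st$lax))))
      rec
    })
  )
  extras <- attr(stacks, "extras")
  if (!is.null(extras)) doc <- c(doc, extras)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a JSON contour file
#'
#' Validates the file against the shipped schema (structural checks:
#' required fields, 3-vectors, >= 3 points per contour, strictly
#' increasing SAX slice indices) and reports every offending record in
#' one error.  Unknown top-level fields are preserved on round-trip via
#' the \code{"extras"} attribute.
#'
#' @param path path to a contour JSON file.
#' @return named list of \code{contour_stack}s keyed
#'   \code{"<phase>.<surface>"}.
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("read_contours: file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  errs <- character(0)
  bad <- function(...) errs[[length(errs) + 1L]] <<- sprintf(...)

  if (is.null(doc$schema_version)) bad("missing schema_version")
  if (!is.null(doc$units) && doc$units != "mm") bad("units must be 'mm'")
  if (is.null(doc$stacks) || !length(doc$stacks)) bad("no stacks in file")

  num3 <- function(x) length(x) == 3L && all(vapply(x, is.numeric, logical(1)))
  out <- list()
  for (si in seq_along(doc$stacks)) {
    st <- doc$stacks[[si]]
    where <- sprintf("stack %d", si)
    for (f in c("phase", "surface", "contours"))
      if (is.null(st[[f]])) bad("%s: missing field '%s'", where, f)
    if (length(errs)) next
    sax <- list(); lax <- NULL; idx_seen <- integer(0)
    for (ci in seq_along(st$contours)) {
      rec <- st$contours[[ci]]
      w <- sprintf("%s contour %d", where, ci)
      if (is.null(rec$view) || !rec$view %in% c("SAX", "LAX")) {
        bad("%s: view must be 'SAX' or 'LAX'", w); next
      }
      if (is.null(rec$plane) || !num3(rec$plane$origin) ||
          !num3(rec$plane$axis_u) || !num3(rec$plane$axis_v)) {
        bad("%s: plane needs numeric length-3 origin/axis_u/axis_v", w); next
      }
      pts <- rec$points
      if (is.null(pts) || length(pts) < 3L ||
          !all(vapply(pts, function(p) length(p) == 2L, logical(1)))) {
        bad("%s: points must be >= 3 pairs of in-plane mm coordinates", w); next
      }
      pmat <- do.call(rbind, lapply(pts, function(p) c(p[[1L]], p[[2L]])))
      plane <- tryCatch(
        image_plane(unlist(rec$plane$origin), unlist(rec$plane$axis_u),
                    unlist(rec$plane$axis_v)),
        error = function(e) { bad("%s: %s", w, conditionMessage(e)); NULL })
      if (is.null(plane)) next
      if (rec$view == "SAX") {
        if (is.null(rec$slice_index)) { bad("%s: SAX record missing slice_index", w); next }
        if (rec$slice_index %in% idx_seen) {
          bad("%s: duplicated slice_index %d", w, rec$slice_index); next
        }
        idx_seen <- c(idx_seen, rec$slice_index)
        ct <- tryCatch(
          planar_contour(plane, pmat, surface = st$surface, phase = st$phase,
                         slice_index = rec$slice_index),
          error = function(e) { bad("%s: %s", w, conditionMessage(e)); NULL })
        if (!is.null(ct)) sax[[length(sax) + 1L]] <- ct
      } else {
        ct <- tryCatch(
          planar_contour(plane, pmat, surface = st$surface, phase = st$phase),
          error = function(e) { bad("%s: %s", w, conditionMessage(e)); NULL })
        if (!is.null(ct)) lax <- ct
      }
    }
    if (length(idx_seen) && any(diff(sort(idx_seen)) == 0))
      bad("%s: duplicated SAX slice_index", where)
    if (!length(errs)) {
      sax <- sax[order(vapply(sax, `[[`, integer(1), "slice_index"))]
      out[[paste(st$phase, st$surface, sep = ".")]] <- contour_stack(
        sax, lax,
        slice_thickness = if (is.null(st$slice_thickness_mm)) NULL else st$slice_thickness_mm,
        gap = if (is.null(st$gap_mm)) 0 else st$gap_mm)
    }
  }
  if (length(errs))
    stop("contour file validation failed:\n  - ", paste(errs, collapse = "\n  - "))
  known <- c("schema_version", "subject_id", "units", "stacks")
  extras <- doc[setdiff(names(doc), known)]
  if (length(extras)) attr(out, "extras") <- extras
  attr(out, "subject_id") <- doc$subject_id
  out
}
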