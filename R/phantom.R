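## Synthetic LV phantom laboratory: parametric star-shaped surfaces with
## computable ground-truth volume, resliced into SAX stacks and LAX planes
## at arbitrary orientations, plus breath-hold misregistration simulation
## and the slice-count ablation experiment.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded package operations do
#' not disturb the caller's RNG stream.  A \code{NULL} seed evaluates the
#' expression against the current stream.
#'
#' @param seed integer seed or \code{NULL}.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Define a parametric LV-like phantom
#'
#' All shapes are star-shaped about their long axis (the body-frame z
#' axis, semi-length \code{c}): every ray perpendicular from the axis hits
#' the surface exactly once, so any reslicing plane yields a simple closed
#' contour.  Shape families:
#' \describe{
#'   \item{ellipsoid}{semi-axes a, b (transverse) and c (long).}
#'   \item{perturbed-ellipsoid}{ellipsoid whose transverse radius is
#'     modulated by low-order angular harmonics, largest at mid-cavity and
#'     vanishing at the tips.}
#'   \item{superellipsoid}{elliptical cross-sections with the flat-topped
#'     axial profile (1 - |z/c|^p)^(1/p); large p approaches a cylinder
#'     with rounded shoulders.}
#'   \item{cylinder}{constant cross-section with flat caps at z = +/- c.}
#' }
#'
#' @param shape one of \code{"ellipsoid"}, \code{"perturbed-ellipsoid"},
#'   \code{"superellipsoid"}, \code{"cylinder"}.
#' @param a,b,c semi-axes in mm (long axis c).
#' @param perturb named numeric vector of harmonic amplitudes (names are
#'   the angular orders, e.g. \code{c("2" = 0.05, "3" = 0.04)}); each
#'   amplitude must be <= 0.15 and their sum < 0.5 so the surface stays
#'   star-shaped.  Only meaningful for \code{"perturbed-ellipsoid"}.
#' @param phases harmonic phase offsets (radians); drawn reproducibly from
#'   \code{seed} when \code{NULL}.
#' @param exponent axial-profile exponent p for superellipsoids.
#' @param wall_thickness epicardial shell thickness in mm (see
#'   \code{\link{epicardial_spec}}).
#' @param rotation 3 x 3 rotation matrix posing the phantom in patient
#'   space; \code{translation} length-3 mm offset.
#' @param seed integer controlling the harmonic phases.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c("ellipsoid", "perturbed-ellipsoid",
                                   "superellipsoid", "cylinder"),
                         a = 20, b = 20, c = 45,
                         perturb = NULL, phases = NULL, exponent = 4,
                         wall_thickness = 8,
                         rotation = diag(3), translation = c(0, 0, 0),
                         seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(a > 0, b > 0, c > 0, wall_thickness >= 0, exponent >= 2)
  if (shape == "perturbed-ellipsoid") {
    if (is.null(perturb)) perturb <- c("2" = 0.05, "3" = 0.04)
    if (is.null(names(perturb)) || anyNA(suppressWarnings(as.integer(names(perturb)))))
      stop("phantom_spec: perturb must be named by integer harmonic order")
    if (any(abs(perturb) > 0.15))
      stop("invalid-phantom: perturbation amplitudes must be <= 0.15")
    if (sum(abs(perturb)) >= 0.5)
      stop("invalid-phantom: summed perturbation amplitudes break star-shapedness")
    if (is.null(phases))
      phases <- with_seed(seed, stats::runif(length(perturb), 0, 2 * pi))
    stopifnot(length(phases) == length(perturb))
  } else {
    perturb <- numeric(0); phases <- numeric(0)
  }
  structure(
    list(shape = shape, a = a, b = b, c = c,
         perturb = perturb, phases = phases, exponent = exponent,
         wall_thickness = wall_thickness,
         rotation = rotation, translation = as.numeric(translation),
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec [%s]: semi-axes (%.1f, %.1f, %.1f) mm", x$shape,
              x$a, x$b, x$c))
  if (length(x$perturb))
    cat(", harmonics (", paste(sprintf("k=%s: %.3f", names(x$perturb), x$perturb),
                               collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Outer (epicardial) shell of a phantom
#'
#' The epicardial surface is the same shape family with every semi-axis
#' grown by the wall thickness, so the enclosed-volume difference stands
#' in for myocardial volume.
#'
#' @param spec a \code{phantom_spec}.
#' @return a \code{phantom_spec} for the outer surface.
#' @export
epicardial_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  w <- spec$wall_thickness
  spec$a <- spec$a + w; spec$b <- spec$b + w; spec$c <- spec$c + w
  spec$wall_thickness <- 0
  spec
}

## axial radius profile s(z) in [0, 1]; 0 outside the phantom
axial_profile <- function(spec, z) {
  u <- z / spec$c
  switch(spec$shape,
    "cylinder" = as.numeric(abs(u) <= 1),
    "superellipsoid" = pmax(0, 1 - pmin(abs(u), 1)^spec$exponent)^(1 / spec$exponent) *
      (abs(u) <= 1),
    pmax(0, 1 - u^2)^0.5 * (abs(u) <= 1))
}

## transverse surface radius rho(theta, z) in the body frame (vectorised;
## theta and z recycled to common length)
phantom_radius <- function(spec, theta, z) {
  s <- axial_profile(spec, z)
  re <- spec$a * spec$b / sqrt((spec$b * cos(theta))^2 + (spec$a * sin(theta))^2)
  m <- 1
  if (length(spec$perturb)) {
    w <- sin(pi * (z + spec$c) / (2 * spec$c))   # max mid-cavity, 0 at tips
    g <- 0
    ks <- as.integer(names(spec$perturb))
    for (i in seq_along(ks))
      g <- g + spec$perturb[[i]] * cos(ks[i] * theta + spec$phases[i])
    m <- 1 + w * g
  }
  s * re * m
}

world_to_body <- function(spec, pts3) {
  pts3 <- matrix(pts3, ncol = 3L)
  sweep(pts3, 2L, spec$translation) %*% spec$rotation   # == t(R) %*% (p - t)
}

body_to_world <- function(spec, pts3) {
  pts3 <- matrix(pts3, ncol = 3L)
  pts3 %*% t(spec$rotation) + rep(spec$translation, each = nrow(pts3))
}

## vectorised inside test for world-coordinate points (n x 3)
phantom_inside <- function(spec, pts3) {
  b <- world_to_body(spec, pts3)
  r <- sqrt(b[, 1L]^2 + b[, 2L]^2)
  theta <- atan2(b[, 2L], b[, 1L])
  rho <- phantom_radius(spec, theta, b[, 3L])
  abs(b[, 3L]) <= spec$c & r <= rho
}

#' Ground-truth phantom volume
#'
#' Pure ellipsoids and cylinders have closed-form volumes; other shapes
#' are voxelized at the requested resolution (centre-in-surface counting,
#' accuracy of order the resolution).
#'
#' @param spec a \code{phantom_spec}.
#' @param resolution voxel edge in mm (<= 1).
#' @return volume in ml.
#' @export
phantom_true_volume <- function(spec, resolution = 0.5) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (resolution > 1) stop("phantom_true_volume: resolution must be <= 1 mm")
  if (spec$shape == "ellipsoid")
    return(4 / 3 * pi * spec$a * spec$b * spec$c / 1000)
  if (spec$shape == "cylinder")
    return(2 * spec$c * pi * spec$a * spec$b / 1000)
  ## voxelize in the body frame (volume is pose-invariant)
  grow <- 1 + if (length(spec$perturb)) sum(abs(spec$perturb)) else 0
  half_d <- max(spec$a, spec$b) * grow
  xs <- seq(-half_d + resolution / 2, half_d, by = resolution)
  zs <- seq(-spec$c + resolution / 2, spec$c, by = resolution)
  xy <- expand.grid(x = xs, y = xs)
  r <- sqrt(xy$x^2 + xy$y^2)
  theta <- atan2(xy$y, xy$x)
  re <- spec$a * spec$b / sqrt((spec$b * cos(theta))^2 + (spec$a * sin(theta))^2)
  g <- 0
  if (length(spec$perturb)) {
    ks <- as.integer(names(spec$perturb))
    for (i in seq_along(ks))
      g <- g + spec$perturb[[i]] * cos(ks[i] * theta + spec$phases[i])
  }
  count <- 0
  for (z in zs) {
    s <- axial_profile(spec, z)
    if (s <= 0) next
    w <- sin(pi * (z + spec$c) / (2 * spec$c))
    rho <- s * re * (1 + w * g)
    count <- count + sum(r <= rho)
  }
  count * resolution^3 / 1000
}

## boundary contour of the phantom in an arbitrary plane, by in-plane ray
## casting from a seed point; returns NULL if the plane misses the phantom
contour_of_plane <- function(spec, plane, n_vertices, surface, phase,
                             slice_index = NULL) {
  centre <- matrix(plane$origin, ncol = 3L)
  if (!phantom_inside(spec, centre)) return(NULL)
  psi <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  dirs <- outer(cos(psi), plane$axis_u) + outer(sin(psi), plane$axis_v)
  grow <- 1 + if (length(spec$perturb)) sum(abs(spec$perturb)) else 0
  r_hi <- rep(2 * max(spec$a, spec$b, spec$c) * grow, n_vertices)
  r_lo <- rep(0, n_vertices)
  for (it in seq_len(52L)) {
    mid <- (r_lo + r_hi) / 2
    pts <- dirs * mid + rep(plane$origin, each = n_vertices)
    ins <- phantom_inside(spec, pts)
    r_lo[ins] <- mid[ins]
    r_hi[!ins] <- mid[!ins]
  }
  r <- (r_lo + r_hi) / 2
  if (any(r < 1e-6)) return(NULL)
  planar_contour(plane, cbind(r * cos(psi), r * sin(psi)),
                 surface = surface, phase = phase, slice_index = slice_index)
}

#' Reslice a phantom into a SAX stack plus one LAX contour
#'
#' SAX planes are perpendicular to the phantom's long axis, uniformly
#' spaced base (slice 0) to apex; tapering shapes keep a small margin at
#' each tip so every slice is a proper closed ring, while cylinders are
#' cut cap-to-cap.  The LAX plane contains (or, when tilted, pivots at the
#' centre of) the long axis at the requested rotation about it.
#'
#' @param spec a \code{phantom_spec}.
#' @param sax_count number of SAX slices (>= 2).
#' @param sax_spacing slice spacing in mm; computed from the covered
#'   extent when \code{NULL}.
#' @param lax_orientation rotation of the LAX plane about the long axis:
#'   \code{"4CH"} (0 deg), \code{"2CH"} (90 deg), or degrees.
#' @param lax_tilt obliquity in degrees: rotation of the LAX plane about
#'   its in-plane transverse axis, pivoted at the centre of the covered
#'   extent (0 = plane contains the long axis).
#' @param n_vertices vertices per SAX contour (default 96).
#' @param lax_vertices vertices of the LAX contour (default 192).
#' @param margins basal/apical tip margins as fractions of the long
#'   semi-axis; default 0.05 for tapering shapes, 0 for cylinders.
#' @param surface,phase labels stamped on the contours.
#' @return a \code{contour_stack}; slices whose plane misses the phantom
#'   are omitted with a warning.
#' @export
reslice <- function(spec, sax_count, sax_spacing = NULL,
                    lax_orientation = "4CH", lax_tilt = 0,
                    n_vertices = 96, lax_vertices = 192, margins = NULL,
                    surface = "endocardium", phase = "ED") {
  stopifnot(inherits(spec, "phantom_spec"), sax_count >= 2)
  if (is.null(margins))
    margins <- if (spec$shape == "cylinder") c(0, 0) else c(0.05, 0.05)
  z_top <- spec$c * (1 - margins[1L])
  z_bot <- -spec$c * (1 - margins[2L])
  if (is.null(sax_spacing)) {
    sax_spacing <- (z_top - z_bot) / (sax_count - 1)
  } else {
    mid <- (z_top + z_bot) / 2
    z_top <- mid + (sax_count - 1) * sax_spacing / 2
  }
  z_mid <- z_top - (sax_count - 1) * sax_spacing / 2

  sax <- list()
  for (j in seq_len(sax_count) - 1L) {
    zj <- z_top - j * sax_spacing
    ## snap round-off onto the caps so cap-to-cap stacks keep both ends
    if (abs(zj) > spec$c && abs(zj) - spec$c < 1e-9 * spec$c)
      zj <- sign(zj) * spec$c
    if (axial_profile(spec, zj) <= 0 || abs(zj) > spec$c) {
      warning(sprintf("SAX slice %d at z = %.1f mm misses the phantom; omitted", j, zj))
      next
    }
    theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
    rho <- phantom_radius(spec, theta, zj)
    plane <- image_plane(drop(body_to_world(spec, c(0, 0, zj))),
                         as.numeric(spec$rotation %*% c(1, 0, 0)),
                         as.numeric(spec$rotation %*% c(0, 1, 0)))
    sax[[length(sax) + 1L]] <- planar_contour(
      plane, cbind(rho * cos(theta), rho * sin(theta)),
      surface = surface, phase = phase, slice_index = j)
  }
  if (length(sax) < 2L)
    stop("reslice: fewer than 2 SAX planes intersect the phantom")

  alpha <- lax_angle(lax_orientation)
  tau <- lax_tilt * pi / 180
  u_b <- c(cos(alpha), sin(alpha), 0)
  v_b <- c(sin(alpha) * sin(tau), -cos(alpha) * sin(tau), cos(tau))
  lax_origin_b <- c(0, 0, if (tau != 0) z_mid else 0)
  lax_plane <- image_plane(drop(body_to_world(spec, lax_origin_b)),
                           as.numeric(spec$rotation %*% u_b),
                           as.numeric(spec$rotation %*% v_b))
  if (tau == 0) {
    ## plane contains the long axis: build the contour from the exact
    ## surface profile u = +/- rho(alpha, z).  Chebyshev-spaced z hits the
    ## tips (and any flat-cap corners) exactly and samples the boundary
    ## densely where it turns.
    K <- max(8L, floor(lax_vertices / 2))
    zk <- spec$c * cos(pi * (0:K) / K)            # +c .. -c
    right <- cbind(phantom_radius(spec, alpha, zk), zk)
    left <- cbind(-phantom_radius(spec, alpha + pi, rev(zk)), rev(zk))
    lax <- planar_contour(lax_plane, rbind(right, left),
                          surface = surface, phase = phase)
  } else {
    lax <- contour_of_plane(spec, lax_plane, lax_vertices, surface, phase)
    if (is.null(lax))
      stop("reslice: LAX plane misses the phantom")
  }

  contour_stack(sax, lax, slice_thickness = sax_spacing, gap = 0)
}

lax_angle <- function(lax_orientation) {
  if (is.character(lax_orientation)) {
    switch(toupper(lax_orientation),
           "4CH" = 0, "2CH" = pi / 2,
           stop("reslice: unknown LAX orientation label; use '4CH', '2CH' or degrees"))
  } else {
    as.numeric(lax_orientation) * pi / 180
  }
}

#' Breath-hold motion model
#'
#' Per-slice rigid displacement bounds for simulated breath-hold
#' misregistration: superior-inferior (along the LV long axis) and
#' anterior-posterior (transverse) maxima, with draws uniform in
#' \code{[-max, +max]} independently per slice.
#'
#' @param max_si maximum superior-inferior displacement (mm, default 18).
#' @param max_ap maximum anterior-posterior displacement (mm, default 2.5).
#' @param seed integer seed making the draws reproducible; \code{NULL}
#'   uses the caller's RNG stream.
#' @return object of class \code{motion_model}.
#' @export
motion_model <- function(max_si = 18, max_ap = 2.5, seed = NULL) {
  stopifnot(max_si >= 0, max_ap >= 0)
  structure(list(max_si = max_si, max_ap = max_ap,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "motion_model")
}

#' Simulate breath-hold misregistration on a contour stack
#'
#' Every slice (each SAX contour and the LAX contour) is acquired in its
#' own breath-hold, so each is rigidly translated by an independent
#' uniform draw along the long axis (SI) and transversely (AP).  Contour
#' shapes and areas are preserved; only their spatial registration
#' degrades.  The drawn offsets are recorded in the returned stack's
#' \code{motion_offsets} field.
#'
#' @param stack a \code{contour_stack}.
#' @param motion a \code{motion_model}.
#' @return the translated \code{contour_stack}.
#' @export
apply_breathhold_misregistration <- function(stack, motion) {
  stopifnot(inherits(stack, "contour_stack"), inherits(motion, "motion_model"))
  n <- length(stack$sax) + as.integer(!is.null(stack$lax))
  draws <- with_seed(motion$seed, {
    cbind(si = stats::runif(n, -motion$max_si, motion$max_si),
          ap = stats::runif(n, -motion$max_ap, motion$max_ap))
  })
  ax <- stack_axis(stack)
  ap_dir <- stack$sax[[1L]]$plane$axis_v   # transverse surrogate for AP
  for (k in seq_along(stack$sax)) {
    shift <- draws[k, "si"] * ax + draws[k, "ap"] * ap_dir
    stack$sax[[k]] <- transform_contour(stack$sax[[k]], translation = shift)
  }
  if (!is.null(stack$lax)) {
    shift <- draws[n, "si"] * ax + draws[n, "ap"] * ap_dir
    stack$lax <- transform_contour(stack$lax, translation = shift)
  }
  stack$motion_offsets <- data.frame(
    slice = c(vapply(stack$sax, `[[`, integer(1), "slice_index"),
              if (!is.null(stack$lax)) NA_integer_),
    si = draws[, "si"], ap = draws[, "ap"])
  stack
}

#' Default phantom cohort
#'
#' Five mildly perturbed ellipsoids with LV-scale semi-axes (transverse
#' 17-24 mm, long 40-50 mm, cavity volumes roughly 60-120 ml) and
#' low-order harmonic perturbations of amplitude 0.02-0.08, standing in
#' for a small set of real hearts.
#'
#' @param n number of phantoms.
#' @param seed integer seed.
#' @return list of \code{phantom_spec}s.
#' @export
phantom_cohort <- function(n = 5, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      a <- stats::runif(1, 17, 24)
      b <- a * stats::runif(1, 0.9, 1.1)
      cc <- stats::runif(1, 40, 50)
      amp <- c("2" = stats::runif(1, 0.03, 0.08), "3" = stats::runif(1, 0.02, 0.06))
      ph <- stats::runif(2, 0, 2 * pi)
      phantom_spec("perturbed-ellipsoid", a = a, b = b, c = cc,
                   perturb = amp, phases = ph, seed = seed + i)
    })
  })
}

#' Slice-count ablation experiment
#'
#' Reslices each phantom into a dense SAX stack plus one LAX contour,
#' retains uniformly covering subsets of n slices, estimates the volume
#' with each method, and reports the percent error against the phantom's
#' ground-truth volume.  With a \code{motion_model}, each repetition
#' applies fresh per-slice breath-hold displacements to the retained
#' slices before estimation.
#'
#' @param specs a \code{phantom_spec} or list of them.
#' @param n_values SAX slice counts to test.
#' @param methods subset of \code{c("trapezoidal", "msimp")}.
#' @param repetitions repeated motion draws per phantom (1 when
#'   \code{motion} is \code{NULL}).
#' @param seed integer seed for all randomness in the experiment.
#' @param motion optional \code{motion_model} (its own seed is ignored
#'   here; draws come from the experiment stream).
#' @param sax_count dense stack size before subsetting.
#' @param lax_orientation passed to \code{\link{reslice}}.
#' @param truth_resolution voxel size (mm) for ground-truth volumes.
#' @param include_basal_virtual,oblique_correction passed to
#'   \code{\link{trapezoidal_volume}}.
#' @return data.frame with one row per (method, n_slices): mean and SD of
#'   percent error, plus the per-case table in \code{attr(., "cases")}.
#' @export
run_slice_ablation <- function(specs, n_values = c(4, 6, 8, 10, 12),
                               methods = c("trapezoidal", "msimp"),
                               repetitions = 1, seed = 1L, motion = NULL,
                               sax_count = 12, lax_orientation = "4CH",
                               truth_resolution = 0.5,
                               include_basal_virtual = FALSE,
                               oblique_correction = TRUE) {
  if (inherits(specs, "phantom_spec")) specs <- list(specs)
  methods <- match.arg(methods, c("trapezoidal", "msimp"), several.ok = TRUE)
  if (any(n_values > sax_count)) stop("invalid-count: n_values exceed sax_count")
  truths <- vapply(specs, phantom_true_volume, numeric(1),
                   resolution = truth_resolution)
  if (!is.null(motion)) motion$seed <- NULL   # draws come from the stream
  cases <- with_seed(seed, {
    rows <- list()
    for (p in seq_along(specs)) {
      dense <- reslice(specs[[p]], sax_count = sax_count,
                       lax_orientation = lax_orientation)
      for (r in seq_len(if (is.null(motion)) 1L else repetitions)) {
        ## every dense-stack slice is acquired in its own breath-hold;
        ## slice selection then works on the acquired (displaced) stack,
        ## as in practice where unusable slices are excluded first
        acq <- dense
        if (!is.null(motion)) {
          acq <- apply_breathhold_misregistration(acq, motion)
          acq <- suppressWarnings(drop_chordless_slices(acq))
          acq <- sort_stack_axially(acq)
        }
        for (k in seq_along(n_values)) {
          st <- select_slice_subset(acq, min(n_values[k], length(acq$sax)))
          for (m in methods) {
            est <- switch(m,
              trapezoidal = trapezoidal_volume(
                st, include_basal_virtual = include_basal_virtual,
                oblique_correction = oblique_correction)$total,
              msimp = msimp_volume(st)$total)
            rows[[length(rows) + 1L]] <- data.frame(
              phantom = p, rep = r, method = m, n_slices = n_values[k],
              estimate_ml = est, truth_ml = truths[p],
              percent_error = 100 * (est - truths[p]) / truths[p])
          }
        }
      }
    }
    do.call(rbind, rows)
  })
  agg <- stats::aggregate(percent_error ~ method + n_slices, data = cases,
                          function(e) c(mean = mean(e), sd = stats::sd(e),
                                        n = length(e)))
  out <- data.frame(method = agg$method, n_slices = agg$n_slices,
                    mean_error = agg$percent_error[, "mean"],
                    sd_error = agg$percent_error[, "sd"],
                    n_cases = agg$percent_error[, "n"])
  out <- out[order(out$method, out$n_slices), ]
  rownames(out) <- NULL
  attr(out, "cases") <- cases
  out
}
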