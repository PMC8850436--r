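#' Template geometry of the midsagittal vocal-tract phantom
#'
#' The phantom models the vocal-tract air channel as a bent tube in the
#' midsagittal plane: a vertical pharyngeal limb, a horizontal oral limb and a
#' quarter-circle bend joining them, all carried by a centerline offset by a
#' half-width on either side.  Coordinates are in mm with the x axis pointing
#' rightward (posterior) and the y axis pointing downward, matching the pixel
#' convention of the rendered images (origin at the top-left pixel center).
#' The anatomical origin used for isotropic scaling is a fixed mid-tract
#' landmark near the velopharyngeal bend, so that overall size changes
#' expand the tract around its middle rather than merely elongating the
#' pharynx (which is the larynx-height mode's job).
#'
#' @param ... named overrides of individual template constants.
#' @return A list of template constants (all in mm unless noted):
#'   \code{pharynx_x}, \code{oral_y} (limb centerlines), \code{bend_radius},
#'   \code{glottis_y} (baseline), \code{lips_x}, \code{half_width},
#'   \code{origin} (hard-palate landmark, length-2), \code{larynx_excursion}
#'   (centerline length change at |larynx_height| = 1),
#'   \code{bump_amp}, \code{bump_amp_gain}, \code{bump_sigma},
#'   \code{bump_center_offset}, \code{bump_travel} (tongue-constriction
#'   geometry), \code{curvature_gain} (relative bend-radius change at
#'   |curvature| = 1) and \code{step_mm} (contour sampling step).
#' @export
vt_template <- function(...) {
  tpl <- list(
    pharynx_x        = 120,
    oral_y           = 100,
    bend_radius      = 30,
    glottis_y        = 185,
    lips_x           = 40,
    half_width       = 11,
    origin           = c(95, 150),
    larynx_excursion = 15,
    bump_amp         = 5,
    bump_amp_gain    = 2,
    bump_pos_gain    = 10,
    bump_sigma       = 11,
    bump_center_offset = 18,
    curvature_gain   = 0.25,
    step_mm          = 1.25
  )
  utils::modifyList(tpl, list(...))
}

#' Construct a vocal-tract shape parameter set
#'
#' The five parameters are the interpreted deformation modes of the phantom:
#' tongue position (back/front constriction location along the inner wall),
#' larynx height (raised/lowered larynx, i.e. shorter/longer tract), global
#' body scale, tongue shape (constriction amplitude) and vocal-tract
#' curvature (bend radius).
#'
#' @param tongue_position back (-1) to front (+1), dimensionless.
#' @param larynx_height lowered (-1) to raised (+1); maps linearly to a
#'   centerline length change of \code{larynx_excursion} mm per unit.
#' @param body_scale global isotropic scale about the hard-palate landmark
#'   (> 0); 1 is the template size.
#' @param tongue_shape flat (-1) to domed (+1) tongue constriction.
#' @param curvature tighter (-1) to wider (+1) bend.
#' @return An object of class \code{"shape_params"}.
#' @export
shape_params <- function(tongue_position = 0, larynx_height = 0,
                         body_scale = 1, tongue_shape = 0, curvature = 0) {
  p <- list(tongue_position = tongue_position, larynx_height = larynx_height,
            body_scale = body_scale, tongue_shape = tongue_shape,
            curvature = curvature)
  validate_shape_params(p)
  structure(p, class = "shape_params")
}

validate_shape_params <- function(p) {
  for (f in c("tongue_position", "larynx_height", "tongue_shape", "curvature")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < -1 || v > 1)
      stop("shape parameter '", f, "' must be a single value in [-1, 1]",
           call. = FALSE)
  }
  if (!is.numeric(p$body_scale) || length(p$body_scale) != 1L ||
      is.na(p$body_scale) || p$body_scale <= 0)
    stop("shape parameter 'body_scale' must be a single value > 0",
         call. = FALSE)
  invisible(p)
}

## Centerline of the bent tube, parametrized by arc length s from the glottis
## (s = 0) to the lips.  Returns position and the inward unit normal (pointing
## to the tongue-root/tongue side of the channel) at each requested s.
vt_centerline <- function(s, larynx_height = 0, curvature = 0,
                          tpl = vt_template()) {
  R  <- tpl$bend_radius * (1 + tpl$curvature_gain * curvature)
  gy <- tpl$glottis_y - tpl$larynx_excursion * larynx_height
  s_pb <- gy - (tpl$oral_y + R)        # glottis -> bend tangent (vertical limb)
  s_po <- s_pb + (pi / 2) * R          # -> oral tangent point
  s_li <- s_po + (tpl$pharynx_x - R - tpl$lips_x)  # -> lips
  cx <- tpl$pharynx_x - R              # arc center
  cy <- tpl$oral_y + R

  x <- y <- nx <- ny <- numeric(length(s))
  seg1 <- s <= s_pb                    # pharyngeal limb (going up)
  x[seg1] <- tpl$pharynx_x
  y[seg1] <- gy - s[seg1]
  nx[seg1] <- -1; ny[seg1] <- 0        # inward = anterior

  seg2 <- s > s_pb & s <= s_po         # bend, angle 0 -> -pi/2 about (cx, cy)
  a <- -(s[seg2] - s_pb) / R
  x[seg2] <- cx + R * cos(a)
  y[seg2] <- cy + R * sin(a)
  nx[seg2] <- -cos(a); ny[seg2] <- -sin(a)  # inward = toward arc center

  seg3 <- s > s_po                     # oral limb (going forward/left)
  x[seg3] <- (tpl$pharynx_x - R) - (s[seg3] - s_po)
  y[seg3] <- tpl$oral_y
  nx[seg3] <- 0; ny[seg3] <- 1         # inward = downward (tongue below)

  list(x = x, y = y, nx = nx, ny = ny,
       s_pb = s_pb, s_po = s_po, length = s_li)
}

## Total centerline length for given parameters (closed form).
vt_centerline_length <- function(params, tpl = vt_template()) {
  R  <- tpl$bend_radius * (1 + tpl$curvature_gain * params$curvature)
  gy <- tpl$glottis_y - tpl$larynx_excursion * params$larynx_height
  base <- (gy - (tpl$oral_y + R)) + (pi / 2) * R +
    (tpl$pharynx_x - R - tpl$lips_x)
  base * params$body_scale
}

## Tongue-constriction profile along the centerline: a Gaussian bump on the
## inner (tongue) wall.  Tongue shape scales the symmetric (Gaussian) lobe;
## tongue position adds the antisymmetric first-derivative lobe, tilting
## the constriction forward (toward the lips, +) or backward into the
## tongue root (-) — the linearized form of sliding the constriction.  The
## bump is anchored to the oral tangent point (d_rel = s - s_po), so it
## does not move when the larynx is raised or lowered, and is tapered to
## zero over the last 10 mm before the lips so the rounded lip cap joins
## the walls continuously.
vt_bump <- function(d_rel, dist_to_lips, tongue_position, tongue_shape,
                    tpl = vt_template()) {
  u <- (d_rel - tpl$bump_center_offset) / tpl$bump_sigma
  g <- exp(-u^2 / 2)
  w <- pmin(pmax(dist_to_lips / 10, 0), 1)
  taper <- w * w * (3 - 2 * w)
  ## resting constriction + volume-preserving doming (tongue_shape; the
  ## dome rises while the margins dip) + forward/backward tilt
  ## (tongue_position)
  (tpl$bump_amp * g +
     tpl$bump_amp_gain * tongue_shape * (1 - u^2) * g +
     tpl$bump_pos_gain * tongue_position * u * g) * taper
}

#' Generate a midsagittal vocal-tract air-channel contour
#'
#' Builds the closed boundary of the phantom air channel for a given shape
#' parameter set: inner (tongue-side) wall from glottis to lips, a rounded
#' lip cap, outer (palate/posterior) wall back to the glottis, and a rounded
#' glottis cap.  The contour is simple, closed, and deterministic in its
#' parameters.  With all parameters at zero and \code{body_scale = 1} it is
#' the template contour.
#'
#' @param params a \code{\link{shape_params}} object (or plain list with the
#'   same fields).
#' @param tpl template constants, see \code{\link{vt_template}}.
#' @return A \code{"vt_contour"} object: an n x 2 matrix of (x_mm, y_mm)
#'   points with attributes \code{closed = TRUE} and \code{frame_index}.
#' @export
make_vocal_tract_contour <- function(params, tpl = vt_template()) {
  validate_shape_params(params)
  h <- params$larynx_height; cv <- params$curvature
  w <- tpl$half_width
  probe <- vt_centerline(0, h, cv, tpl)
  L <- probe$length; s_pb <- probe$s_pb; s_po <- probe$s_po

  ## per-segment sampling: the oral limb and bend are sampled at positions
  ## fixed relative to the oral tangent point, so raising or lowering the
  ## larynx changes only pharyngeal-limb points.
  n1 <- max(8L, ceiling(s_pb / tpl$step_mm))
  n2 <- max(8L, ceiling((s_po - s_pb) / tpl$step_mm))
  n3 <- max(8L, ceiling((L - s_po) / tpl$step_mm))
  s <- c(seq(0, s_pb, length.out = n1 + 1L),
         seq(s_pb, s_po, length.out = n2 + 1L)[-1L],
         seq(s_po, L, length.out = n3 + 1L)[-1L])
  n_wall <- length(s)
  cl <- vt_centerline(s, h, cv, tpl)
  b <- vt_bump(s - s_po, L - s, params$tongue_position, params$tongue_shape,
               tpl)

  inner_x <- cl$x + cl$nx * (w - b)
  inner_y <- cl$y + cl$ny * (w - b)
  outer_x <- cl$x - cl$nx * w
  outer_y <- cl$y - cl$ny * w

  ## rounded caps: semicircles about the centerline ends
  cap <- function(cx0, cy0, a_from, a_to, n = 12L) {
    a <- seq(a_from, a_to, length.out = n + 2L)[2:(n + 1L)]
    cbind(cx0 + w * cos(a), cy0 + w * sin(a))
  }
  ## lip cap: from inner wall end (normal (0,1): angle pi/2) sweeping through
  ## the anterior point (angle pi, x minimal) to the outer end (angle 3pi/2).
  lip  <- cap(cl$x[n_wall], cl$y[n_wall], pi / 2, 3 * pi / 2)
  ## glottis cap: outer wall end at angle pi/2 + pi = ... outer is -n = (+1,0)
  ## angle 0; inner end angle pi; sweep through +pi/2 (bottom, y maximal).
  glot <- cap(cl$x[1L], cl$y[1L], 0, pi)

  xy <- rbind(cbind(inner_x, inner_y), lip,
              cbind(rev(outer_x), rev(outer_y)), glot)
  colnames(xy) <- c("x", "y")

  ## isotropic scaling about the fixed hard-palate landmark
  if (params$body_scale != 1) {
    xy[, 1] <- tpl$origin[1] + params$body_scale * (xy[, 1] - tpl$origin[1])
    xy[, 2] <- tpl$origin[2] + params$body_scale * (xy[, 2] - tpl$origin[2])
  }
  vt_contour(xy, closed = TRUE)
}

#' Create a vocal-tract outline object
#'
#' @param xy n x 2 numeric matrix of (x_mm, y_mm) points, at least 20 rows
#'   for closed outlines; the final point must not repeat the first.
#' @param closed logical; is the outline a closed boundary?
#' @param frame_index integer frame label carried through the pipeline.
#' @return An object of class \code{"vt_contour"}.
#' @export
vt_contour <- function(xy, closed = TRUE, frame_index = NA_integer_) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("outline must be an n x 2 matrix", call. = FALSE)
  colnames(xy) <- c("x", "y")
  if (closed && nrow(xy) >= 2L && all(xy[1L, ] == xy[nrow(xy), ]))
    xy <- xy[-nrow(xy), , drop = FALSE]
  if (closed && nrow(xy) < 20L)
    stop("closed outline needs at least 20 points", call. = FALSE)
  structure(xy, closed = closed, frame_index = as.integer(frame_index),
            class = c("vt_contour", "matrix", "array"))
}

#' @export
print.vt_contour <- function(x, ...) {
  cat(sprintf("vt_contour: %d points, %s, length %.1f mm\n", nrow(x),
              if (isTRUE(attr(x, "closed"))) "closed" else "open",
              contour_length(x)))
  invisible(x)
}

#' Polyline length of an outline (perimeter if closed)
#' @param outline a \code{vt_contour}.
#' @return length in mm.
#' @export
contour_length <- function(outline) {
  xy <- unclass(outline)
  if (isTRUE(attr(outline, "closed"))) xy <- rbind(xy, xy[1L, ])
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}

## Signed area via the shoelace formula.  Positive sign is the package's
## canonical outline orientation (the direction the generator emits:
## glottis -> lips along the tongue-side wall, lips -> glottis along the
## palate-side wall; counter-clockwise as seen on screen with y down).
contour_signed_area <- function(outline) {
  xy <- unclass(outline)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Numerically integrate the air-channel centerline length of a contour
#'
#' Estimates the medial length of a generated channel contour by averaging
#' the inner and outer wall polylines.  For contours produced by
#' \code{\link{make_vocal_tract_contour}} this recovers the analytic
#' centerline length to sub-mm accuracy; it exists so that length changes can
#' be measured from geometry alone, independently of the generator's
#' closed-form expression.
#'
#' @param params a \code{\link{shape_params}} object.
#' @param n number of quadrature samples along the centerline.
#' @param tpl template constants.
#' @return centerline length in mm.
#' @export
measure_centerline_length <- function(params, n = 2000L, tpl = vt_template()) {
  validate_shape_params(params)
  s <- seq(0, vt_centerline(0, params$larynx_height, params$curvature,
                            tpl)$length,
           length.out = n)
  cl <- vt_centerline(s, params$larynx_height, params$curvature, tpl)
  dl <- sqrt(diff(cl$x)^2 + diff(cl$y)^2)
  sum(dl) * params$body_scale
}

## ---- rigid transforms -----------------------------------------------------

#' Rigid (rotation + translation) in-plane transform
#'
#' Transforms act on mm coordinates as \code{p' = R (p - c) + c + t}, where
#' \code{R} is the rotation by \code{rotation_deg} and \code{c} is a fixed
#' rotation center (by default the field-of-view center of the standard
#' 88 x 110 pixel frame).
#'
#' @param rotation_deg rotation angle in degrees (positive = from +x toward
#'   +y, i.e. visually clockwise with y pointing down).
#' @param tx_mm,ty_mm translation in mm.
#' @param center_mm length-2 rotation center in mm.
#' @return An object of class \code{"rigid_transform"}.
#' @export
rigid_transform <- function(rotation_deg = 0, tx_mm = 0, ty_mm = 0,
                            center_mm = c(87 * 2.5 / 2, 109 * 2.5 / 2)) {
  structure(list(rotation_deg = rotation_deg, tx_mm = tx_mm, ty_mm = ty_mm,
                 center_mm = center_mm),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: %.3f deg, (%.3f, %.3f) mm\n",
              x$rotation_deg, x$tx_mm, x$ty_mm))
  invisible(x)
}

#' Apply a rigid transform to points
#' @param t a \code{rigid_transform}.
#' @param xy n x 2 matrix of (x_mm, y_mm) points.
#' @return transformed n x 2 matrix.
#' @export
transform_points <- function(t, xy) {
  xy <- as.matrix(xy)
  a <- t$rotation_deg * pi / 180
  cx <- t$center_mm[1]; cy <- t$center_mm[2]
  dx <- xy[, 1] - cx; dy <- xy[, 2] - cy
  cbind(cx + cos(a) * dx - sin(a) * dy + t$tx_mm,
        cy + sin(a) * dx + cos(a) * dy + t$ty_mm)
}

#' Invert a rigid transform
#' @param t a \code{rigid_transform}.
#' @return the inverse \code{rigid_transform} (same rotation center).
#' @export
rigid_invert <- function(t) {
  a <- -t$rotation_deg * pi / 180
  rigid_transform(-t$rotation_deg,
                  -(cos(a) * t$tx_mm - sin(a) * t$ty_mm),
                  -(sin(a) * t$tx_mm + cos(a) * t$ty_mm),
                  t$center_mm)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying \code{first}, then
#' \code{second} (both about the same rotation center).
#' @param second,first \code{rigid_transform} objects sharing a center.
#' @return the composed \code{rigid_transform}.
#' @export
rigid_compose <- function(second, first) {
  stopifnot(all(second$center_mm == first$center_mm))
  a2 <- second$rotation_deg * pi / 180
  rigid_transform(second$rotation_deg + first$rotation_deg,
                  cos(a2) * first$tx_mm - sin(a2) * first$ty_mm + second$tx_mm,
                  sin(a2) * first$tx_mm + cos(a2) * first$ty_mm + second$ty_mm,
                  first$center_mm)
}
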