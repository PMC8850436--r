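#' Default rendering configuration of the rtMRI phantom
#'
#' The scene emulates a midsagittal T1-weighted real-time MRI frame: bright
#' soft tissue (head), a very bright cranial arc (skull base) and a column of
#' bright vertebral bodies (the static structures used for registration), and
#' a dark air channel.  Geometry defaults follow the acquisition scale of the
#' study data: 88 x 110 pixels at 2.5 mm in-plane resolution.
#'
#' @return list of scene constants: \code{nx}, \code{ny} (pixels),
#'   \code{pixel_size_mm}, intensities (\code{air}, \code{tissue},
#'   \code{bone}, \code{background}), head ellipse (\code{head_center},
#'   \code{head_axes}), skull arc (\code{skull_center}, \code{skull_r_inner},
#'   \code{skull_r_outer}, \code{skull_angles} in radians), vertebrae
#'   (\code{vert_x}, \code{vert_y}, \code{vert_r}) and \code{frame_rate_hz}.
#' @export
render_config <- function() {
  list(
    nx = 88L, ny = 110L, pixel_size_mm = 2.5,
    air = 10, tissue = 200, bone = 255, background = 0,
    head_center = c(95, 140), head_axes = c(85, 97),
    skull_center = c(95, 120), skull_r_inner = 78, skull_r_outer = 92,
    skull_angles = c(-pi, 0),
    vert_x = 150, vert_y = c(115, 140, 165, 190), vert_r = 8,
    ## smooth intensity inhomogeneity of the bony structures; gives the
    ## registration metric texture beyond edges (real T1 images are not
    ## piecewise constant)
    bone_texture = list(amp = 30, wx_mm = 31, wy_mm = 24),
    frame_rate_hz = 8
  )
}

#' Pixel-center coordinate grids for a frame geometry
#' @param cfg render configuration (see \code{\link{render_config}}).
#' @return list with matrices \code{x}, \code{y} of mm coordinates
#'   (\code{ny} rows x \code{nx} columns; top-left pixel center at (0, 0)).
#' @export
pixel_grid <- function(cfg = render_config()) {
  x <- matrix(rep((seq_len(cfg$nx) - 1) * cfg$pixel_size_mm, each = cfg$ny),
              cfg$ny, cfg$nx)
  y <- matrix(rep((seq_len(cfg$ny) - 1) * cfg$pixel_size_mm, cfg$nx),
              cfg$ny, cfg$nx)
  list(x = x, y = y)
}

#' Even-odd point-in-polygon test
#'
#' Vectorized ray-casting test used to rasterize air-channel outlines.
#'
#' @param px,py numeric vectors of query point coordinates.
#' @param poly n x 2 polygon vertex matrix (closed implicitly).
#' @return logical vector; TRUE where the point lies inside.
#' @export
points_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## Analytic masks of the static scene, evaluated at arbitrary mm coordinates
## (vectors px, py).  Each returns a logical vector.
scene_head <- function(px, py, cfg) {
  ((px - cfg$head_center[1]) / cfg$head_axes[1])^2 +
    ((py - cfg$head_center[2]) / cfg$head_axes[2])^2 <= 1
}

scene_skull <- function(px, py, cfg) {
  dx <- px - cfg$skull_center[1]; dy <- py - cfg$skull_center[2]
  r <- sqrt(dx^2 + dy^2)
  a <- atan2(dy, dx)
  r >= cfg$skull_r_inner & r <= cfg$skull_r_outer &
    a >= cfg$skull_angles[1] & a <= cfg$skull_angles[2]
}

scene_vertebrae <- function(px, py, cfg) {
  out <- rep(FALSE, length(px))
  for (vy in cfg$vert_y)
    out <- out | ((px - cfg$vert_x)^2 + (py - vy)^2 <= cfg$vert_r^2)
  out
}

#' Ground-truth mask of the static structures (skull arc and vertebrae)
#'
#' This is the mask a human analyst would draw around structures that do not
#' move with articulation; it drives rigid registration.  A one-pixel guard
#' dilation is applied so that partial-volume edge pixels are included.
#'
#' @param cfg render configuration.
#' @param dilate_px guard dilation radius in pixels.
#' @return \code{"pixel_mask"} object (logical ny x nx matrix with a
#'   \code{kind} attribute).
#' @export
static_structure_mask <- function(cfg = render_config(), dilate_px = 1L) {
  g <- pixel_grid(cfg)
  m <- matrix(scene_skull(g$x, g$y, cfg) | scene_vertebrae(g$x, g$y, cfg),
              cfg$ny, cfg$nx)
  if (dilate_px > 0)
    m <- ebi_to_mask(EBImage::dilate(ebi_from_mask(m),
                                     EBImage::makeBrush(2L * dilate_px + 1L,
                                                        "disc")))
  pixel_mask(m, kind = "static_structures")
}

#' Construct a pixel mask
#' @param m logical matrix.
#' @param kind one of \code{"static_structures"}, \code{"labile_candidates"},
#'   \code{"tissue"}, \code{"air"}.
#' @return \code{"pixel_mask"} object.
#' @export
pixel_mask <- function(m, kind = "labile_candidates") {
  m <- as.matrix(m)
  storage.mode(m) <- "logical"
  structure(m, kind = kind, class = c("pixel_mask", "matrix", "array"))
}

## EBImage works on transposed numeric images; these two helpers keep the
## row = y, column = x convention of the package consistent.
ebi_from_mask <- function(m) EBImage::Image(t(m) * 1)
ebi_to_mask <- function(img) t(EBImage::imageData(img)) > 0.5

#' Rasterize an outline into a pixel mask
#'
#' @param outline a closed \code{vt_contour} in mm coordinates.
#' @param cfg render configuration defining the pixel grid.
#' @return \code{"pixel_mask"} of pixels whose centers fall inside the
#'   outline, with \code{kind = "air"}.
#' @export
rasterize_outline <- function(outline, cfg = render_config()) {
  g <- pixel_grid(cfg)
  m <- matrix(points_in_polygon(as.vector(g$x), as.vector(g$y),
                                unclass(outline)),
              cfg$ny, cfg$nx)
  pixel_mask(m, kind = "air")
}

#' Render one synthetic rtMRI frame
#'
#' Draws the full scene (head tissue, skull arc, vertebrae, air channel)
#' posed by a rigid transform and adds Gaussian noise.  The scene is
#' evaluated analytically at inverse-transformed pixel centers, so edges
#' stay sharp under any pose.
#'
#' @param outline air-channel \code{vt_contour} in anatomical (reference)
#'   coordinates.
#' @param rigid \code{\link{rigid_transform}} posing the whole scene
#'   (head motion); identity by default.
#' @param noise_sd additive Gaussian noise standard deviation in intensity
#'   units.
#' @param seed integer seed making the noise reproducible.
#' @param cfg render configuration.
#' @param frame_index,labels frame annotation carried on the result.
#' @param oversample subpixel supersampling factor per axis; values > 1
#'   average the scene over a grid within each pixel, emulating
#'   partial-volume edges (1 = point sampling at pixel centers).
#' @return \code{"image_frame"}: list with \code{intensities} (ny x nx
#'   matrix), \code{pixel_size_mm}, \code{frame_index}, \code{labels}.
#' @export
render_frame <- function(outline, rigid = rigid_transform(), noise_sd = 0,
                         seed = 1L, cfg = render_config(),
                         frame_index = NA_integer_, labels = list(),
                         oversample = 3L) {
  seed <- as.integer(seed)   # force before any RNG state handling
  xy <- unclass(outline)
  txy <- transform_points(rigid, xy)
  if (any(txy[, 1] < 0) || any(txy[, 1] > (cfg$nx - 1) * cfg$pixel_size_mm) ||
      any(txy[, 2] < 0) || any(txy[, 2] > (cfg$ny - 1) * cfg$pixel_size_mm))
    stop("outline exits the field of view after transform", call. = FALSE)

  g <- pixel_grid(cfg)
  inv <- rigid_invert(rigid)
  shade <- function(px, py) {
    v <- rep(cfg$background, length(px))
    v[scene_head(px, py, cfg)] <- cfg$tissue
    bone <- scene_skull(px, py, cfg) | scene_vertebrae(px, py, cfg)
    tex <- cfg$bone_texture
    v[bone] <- cfg$bone + tex$amp * sin(2 * pi * px[bone] / tex$wx_mm) *
      sin(2 * pi * py[bone] / tex$wy_mm)
    bb <- px >= min(xy[, 1]) & px <= max(xy[, 1]) &
      py >= min(xy[, 2]) & py <= max(xy[, 2])
    v[bb][points_in_polygon(px[bb], py[bb], xy)] <- cfg$air
    v
  }
  os <- max(1L, as.integer(oversample))
  img <- numeric(cfg$nx * cfg$ny)
  offs <- (seq_len(os) - (os + 1) / 2) / os * cfg$pixel_size_mm
  for (ox in offs) for (oy in offs) {
    p <- transform_points(inv, cbind(as.vector(g$x) + ox,
                                     as.vector(g$y) + oy))
    img <- img + shade(p[, 1], p[, 2])
  }
  img <- matrix(img / (os * os), cfg$ny, cfg$nx)

  if (noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        cfg$ny, cfg$nx)
  }
  image_frame(img, cfg$pixel_size_mm, frame_index, labels)
}

#' Construct an image frame object
#' @param intensities numeric matrix (rows = y, columns = x).
#' @param pixel_size_mm pixel size in mm (> 0).
#' @param frame_index integer frame label.
#' @param labels list of condition labels (speaker_id, word, vt_condition).
#' @return \code{"image_frame"} object.
#' @export
image_frame <- function(intensities, pixel_size_mm = 2.5,
                        frame_index = NA_integer_, labels = list()) {
  intensities <- as.matrix(intensities)
  if (!is.numeric(pixel_size_mm) || pixel_size_mm <= 0)
    stop("pixel_size_mm must be > 0", call. = FALSE)
  structure(list(intensities = intensities, pixel_size_mm = pixel_size_mm,
                 frame_index = as.integer(frame_index), labels = labels),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("image_frame %d: %d x %d px @ %.2f mm\n",
              x$frame_index, ncol(x$intensities), nrow(x$intensities),
              x$pixel_size_mm))
  invisible(x)
}

#' Construct an image series
#' @param frames ny x nx x n numeric array of frame intensities.
#' @param pixel_size_mm pixel size in mm.
#' @param labels data.frame with one row per frame (at least
#'   \code{frame_index, speaker_id, word, vt_condition}).
#' @return \code{"image_series"} object.
#' @export
image_series <- function(frames, pixel_size_mm = 2.5, labels = NULL) {
  stopifnot(length(dim(frames)) == 3L)
  if (is.null(labels))
    labels <- data.frame(frame_index = seq_len(dim(frames)[3]),
                         speaker_id = NA_character_, word = NA_character_,
                         vt_condition = NA_character_)
  stopifnot(nrow(labels) == dim(frames)[3])
  structure(list(frames = frames, pixel_size_mm = pixel_size_mm,
                 labels = labels),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_series: %d frames of %d x %d px @ %.2f mm\n",
              d[3], d[2], d[1], x$pixel_size_mm))
  invisible(x)
}

#' Number of frames in a series
#' @param series an \code{image_series}.
#' @return integer frame count.
#' @export
n_frames <- function(series) dim(series$frames)[3]

#' Extract one frame of a series
#' @param series an \code{image_series}.
#' @param i frame position (1-based).
#' @return \code{"image_frame"}.
#' @export
get_frame <- function(series, i) {
  lab <- as.list(series$labels[i, , drop = FALSE])
  image_frame(series$frames[, , i], series$pixel_size_mm,
              frame_index = lab$frame_index,
              labels = lab[setdiff(names(lab), "frame_index")])
}

## Save and restore the global RNG state so that seeded generators are pure
## functions of their arguments without disturbing the caller's stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
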