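#' Bilinear sampling of a frame at arbitrary mm coordinates
#'
#' @param frame an \code{\link{image_frame}}.
#' @param xy n x 2 matrix of (x_mm, y_mm) sample positions.
#' @param outside value returned for positions outside the field of view.
#' @return numeric vector of interpolated intensities.
#' @export
sample_frame <- function(frame, xy, outside = 0) {
  img <- frame$intensities
  ps <- frame$pixel_size_mm
  ny <- nrow(img); nx <- ncol(img)
  cx <- xy[, 1] / ps          # 0-based continuous column index
  cy <- xy[, 2] / ps
  c0 <- floor(cx); r0 <- floor(cy)
  fx <- cx - c0; fy <- cy - r0
  ok <- c0 >= 0 & c0 <= nx - 2L & r0 >= 0 & r0 <= ny - 2L
  ## clamp for safe indexing; invalid positions overwritten below
  c0c <- pmin(pmax(c0, 0), nx - 2L); r0c <- pmin(pmax(r0, 0), ny - 2L)
  i00 <- r0c + 1L + c0c * ny
  v <- (1 - fx) * (1 - fy) * img[i00] + fx * (1 - fy) * img[i00 + ny] +
    (1 - fx) * fy * img[i00 + 1L] + fx * fy * img[i00 + ny + 1L]
  v[!ok] <- outside
  ## exact edge coordinates (on the last row/column) handled by clamping
  edge <- !ok & cx >= 0 & cx <= nx - 1L & cy >= 0 & cy <= ny - 1L
  if (any(edge)) {
    c0e <- pmin(floor(cx[edge]), nx - 2L)
    r0e <- pmin(floor(cy[edge]), ny - 2L)
    fxe <- cx[edge] - c0e; fye <- cy[edge] - r0e
    i00 <- r0e + 1L + c0e * ny
    v[edge] <- (1 - fxe) * (1 - fye) * img[i00] +
      fxe * (1 - fye) * img[i00 + ny] +
      (1 - fxe) * fye * img[i00 + 1L] + fxe * fye * img[i00 + ny + 1L]
  }
  v
}

#' Resample a frame under a rigid transform
#'
#' Applies the transform to the image content: the output at position x
#' equals the input at \code{t^{-1}(x)} (bilinear interpolation;
#' out-of-field pixels set to 0).  Applying the transform estimated by
#' \code{\link{estimate_rigid_transform}} therefore registers a frame onto
#' its reference.
#'
#' @param frame an \code{\link{image_frame}}.
#' @param t a \code{\link{rigid_transform}}.
#' @return the resampled \code{image_frame}.
#' @export
apply_transform <- function(frame, t) {
  if (t$rotation_deg == 0 && t$tx_mm == 0 && t$ty_mm == 0) return(frame)
  ny <- nrow(frame$intensities); nx <- ncol(frame$intensities)
  g <- pixel_grid(list(nx = nx, ny = ny, pixel_size_mm = frame$pixel_size_mm))
  p <- transform_points(rigid_invert(t), cbind(as.vector(g$x),
                                               as.vector(g$y)))
  image_frame(matrix(sample_frame(frame, p, outside = 0), ny, nx),
              frame$pixel_size_mm, frame$frame_index, frame$labels)
}

#' Estimate the rigid transform registering a frame to a reference
#'
#' Maximizes the normalized cross-correlation between the transformed frame
#' and the reference over the pixels of a static-structure mask (skull,
#' vertebrae), so that articulator movement cannot bias the pose estimate.
#' The search combines a coarse multi-start over rotation with Nelder-Mead
#' refinement and is bounded to +-10 degrees and +-20 mm.
#'
#' @param frame,reference \code{\link{image_frame}}s of equal shape.
#' @param static_mask \code{\link{pixel_mask}} of static structures (same
#'   shape), excluding labile vocal-tract structures.
#' @param rotation_starts initial rotations (degrees) for the multi-start.
#' @param max_rotation_deg,max_translation_mm search bounds.
#' @param blur_sigma_px Gaussian pre-smoothing of both images in pixels;
#'   suppresses rasterization aliasing that would otherwise bias the
#'   correlation peak by a fraction of a degree.  0 disables.
#' @return the registering \code{\link{rigid_transform}} (apply it to
#'   \code{frame} to align it with \code{reference}).
#' @export
estimate_rigid_transform <- function(frame, reference, static_mask,
                                     rotation_starts = c(-6, 0, 6),
                                     max_rotation_deg = 10,
                                     max_translation_mm = 20,
                                     blur_sigma_px = 1) {
  stopifnot(all(dim(frame$intensities) == dim(reference$intensities)),
            all(dim(static_mask) == dim(frame$intensities)))
  idx <- which(static_mask)
  if (stats::sd(reference$intensities[idx]) == 0)
    stop("static mask covers a flat (zero-variance) region; cannot register",
         call. = FALSE)
  if (blur_sigma_px > 0) {
    blur <- function(f) image_frame(
      t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(f$intensities)),
                                          sigma = blur_sigma_px))),
      f$pixel_size_mm, f$frame_index, f$labels)
    frame <- blur(frame); reference <- blur(reference)
  }
  ref_v <- reference$intensities[idx]
  ny <- nrow(frame$intensities)
  ps <- frame$pixel_size_mm
  rows <- (idx - 1L) %% ny; cols <- (idx - 1L) %/% ny
  pts <- cbind(cols * ps, rows * ps)
  ref_c <- ref_v - mean(ref_v)
  ref_ss <- sqrt(sum(ref_c^2))

  neg_ncc <- function(par) {
    if (abs(par[1]) > max_rotation_deg || abs(par[2]) > max_translation_mm ||
        abs(par[3]) > max_translation_mm) return(2)
    ## frame(t^{-1}(x)) at masked x: sample frame at inverse-transformed pts
    t <- rigid_transform(par[1], par[2], par[3])
    v <- sample_frame(frame, transform_points(rigid_invert(t), pts),
                      outside = 0)
    vc <- v - mean(v)
    ss <- sqrt(sum(vc^2))
    if (ss == 0) return(2)
    -sum(vc * ref_c) / (ss * ref_ss)
  }
  best <- NULL
  for (r0 in rotation_starts) {
    fit <- stats::optim(c(r0, 0, 0), neg_ncc, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 400))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ## polish from the best start
  best <- stats::optim(best$par, neg_ncc, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 400))
  rigid_transform(best$par[1], best$par[2], best$par[3])
}

#' Register an image series to a reference frame
#'
#' @param series an \code{\link{image_series}}.
#' @param reference reference \code{\link{image_frame}} (defaults to the
#'   series' first frame, or supply a single representative frame shared
#'   across speakers).
#' @param static_mask static-structure \code{\link{pixel_mask}}.
#' @return list with \code{series} (registered \code{image_series}) and
#'   \code{transforms} (data.frame of per-frame estimates).
#' @export
register_series <- function(series, reference = NULL, static_mask) {
  if (is.null(reference)) reference <- get_frame(series, 1L)
  nf <- n_frames(series)
  out <- series$frames
  tr <- vector("list", nf)
  for (i in seq_len(nf)) {
    f <- get_frame(series, i)
    t <- estimate_rigid_transform(f, reference, static_mask)
    out[, , i] <- apply_transform(f, t)$intensities
    tr[[i]] <- data.frame(frame_index = series$labels$frame_index[i],
                          rotation_deg = t$rotation_deg, tx_mm = t$tx_mm,
                          ty_mm = t$ty_mm)
  }
  list(series = image_series(out, series$pixel_size_mm, series$labels),
       transforms = do.call(rbind, tr))
}

#' Localize candidate vocal-tract pixels by temporal variance
#'
#' Vocal-tract pixels alternate between bright soft tissue and dark air as
#' articulators move, so high temporal variance marks them.  The raw
#' variance mask is cleaned by morphological closing and reduced to its
#' largest connected component; optional hole filling and dilation widen it
#' into the kind of "may sometimes contain vocal tract" candidate region an
#' analyst would draw (always-air pixels have near-zero variance and would
#' otherwise be excluded).
#'
#' @param series a registered \code{\link{image_series}} (>= 2 frames).
#' @param quantile variance quantile defining "high" (0 < q < 1); pixels
#'   strictly above the threshold are kept.
#' @param closing_px radius (pixels) of the morphological closing; 0 skips.
#' @param fill_holes fill enclosed holes of the largest component?
#' @param dilate_px radius (pixels) of a final dilation; 0 skips.
#' @param exclude optional logical mask of pixels that may never be
#'   candidates (static structures, outside the head); applied after
#'   thresholding.
#' @param noise_floor the threshold is raised to at least
#'   \code{noise_floor * median(variance)}, so that pure measurement noise
#'   (whose variance is spatially flat) cannot flood the mask; 0 disables.
#' @return a \code{\link{pixel_mask}} of kind \code{"labile_candidates"}.
#' @export
high_variance_mask <- function(series, quantile = 0.85, closing_px = 1L,
                               fill_holes = FALSE, dilate_px = 0L,
                               exclude = NULL, noise_floor = 8) {
  if (n_frames(series) < 2L)
    stop("need at least 2 frames to compute temporal variance",
         call. = FALSE)
  if (quantile <= 0 || quantile >= 1)
    stop("quantile must be strictly between 0 and 1", call. = FALSE)
  nf <- n_frames(series)
  X <- series$frames
  dim(X) <- c(prod(dim(series$frames)[1:2]), nf)
  v <- rowSums((X - rowMeans(X))^2) / (nf - 1)
  dim(v) <- dim(series$frames)[1:2]
  thr <- max(stats::quantile(v, quantile, names = FALSE),
             noise_floor * stats::median(v))
  m <- v > thr
  if (!is.null(exclude)) m <- m & !exclude
  if (!any(m)) return(pixel_mask(m, kind = "labile_candidates"))
  img <- ebi_from_mask(m)
  if (closing_px > 0)
    img <- EBImage::closing(img, EBImage::makeBrush(2L * closing_px + 1L,
                                                    "disc"))
  lab <- EBImage::bwlabel(img)
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(tab)) {
    keep <- which.max(tab)
    img <- EBImage::Image((EBImage::imageData(lab) == keep) * 1)
  }
  if (fill_holes) img <- EBImage::fillHull(img)
  if (dilate_px > 0)
    img <- EBImage::dilate(img, EBImage::makeBrush(2L * dilate_px + 1L,
                                                   "disc"))
  pixel_mask(ebi_to_mask(img), kind = "labile_candidates")
}

#' Otsu threshold of an intensity sample
#'
#' Maximizes the between-class variance of the two-class split of a
#' histogram — the "simple tissue classification" exploiting air/tissue
#' contrast.
#'
#' @param values numeric intensity sample.
#' @param n_bins histogram resolution.
#' @return the threshold (values strictly above it are the bright class).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  r <- range(values)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(values, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between[-n_bins])]
}

#' Classify candidate pixels into tissue and air
#'
#' Within the candidate region, picks an intensity threshold by between-
#' class variance maximization of the masked histogram; pixels above the
#' threshold are tissue.  When the two classes are poorly separated (the
#' threshold fails to split the masked intensities into classes whose means
#' differ by at least \code{min_contrast}), the output carries a
#' \code{low_contrast} attribute flag.
#'
#' @param frame an \code{\link{image_frame}}.
#' @param candidates candidate \code{\link{pixel_mask}} (nonempty).
#' @param min_contrast minimum air/tissue mean separation (intensity units)
#'   below which the low-contrast flag is raised.
#' @return \code{pixel_mask} of kind \code{"tissue"} (TRUE = tissue within
#'   candidates) with attributes \code{threshold} and \code{low_contrast}.
#' @export
classify_tissue <- function(frame, candidates, min_contrast = 30) {
  if (!any(candidates)) stop("candidate mask is empty", call. = FALSE)
  vals <- frame$intensities[candidates]
  thr <- otsu_threshold(vals)
  tissue <- candidates & (frame$intensities > thr)
  lo <- vals[vals <= thr]; hi <- vals[vals > thr]
  low_contrast <- length(lo) == 0L || length(hi) == 0L ||
    (mean(hi) - mean(lo)) < min_contrast
  out <- pixel_mask(tissue, kind = "tissue")
  attr(out, "threshold") <- thr
  attr(out, "low_contrast") <- low_contrast
  out
}

#' Extract the air-channel outline from a tissue classification
#'
#' Takes the largest connected air component (candidate pixels not
#' classified as tissue), and traces its boundary at sub-pixel resolution
#' with marching squares (the 0.5 level set of the component indicator),
#' returning an ordered closed outline in mm.
#'
#' @param tissue tissue \code{\link{pixel_mask}} from
#'   \code{\link{classify_tissue}}.
#' @param candidates the candidate mask the classification was run in.
#' @param frame_index frame label for the outline.
#' @param pixel_size_mm pixel size.
#' @param min_area_px air components smaller than this are ignored as
#'   artifacts.
#' @return a closed \code{\link{vt_contour}} in canonical orientation.
#' @export
extract_outline <- function(tissue, candidates, frame_index = NA_integer_,
                            pixel_size_mm = 2.5, min_area_px = 10L) {
  air <- candidates & !tissue
  if (!any(air)) stop("no air component inside the candidate region",
                      call. = FALSE)
  lab <- EBImage::bwlabel(ebi_from_mask(air))
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  if (max(tab) < min_area_px)
    stop("largest air component smaller than ", min_area_px, " px",
         call. = FALSE)
  comp <- t(EBImage::imageData(lab)) == which.max(tab)
  mask_outline(comp, pixel_size_mm, frame_index)
}

#' Sub-pixel boundary of a binary mask
#'
#' Marching-squares contour of the mask indicator at level 0.5: boundary
#' points lie halfway between inside and outside pixel centers, linearly
#' interpolated.
#'
#' @param mask logical matrix (rows = y, columns = x).
#' @param pixel_size_mm pixel size.
#' @param frame_index frame label.
#' @return closed \code{\link{vt_contour}} (largest ring if several).
#' @export
mask_outline <- function(mask, pixel_size_mm = 2.5,
                         frame_index = NA_integer_) {
  ny <- nrow(mask); nx <- ncol(mask)
  ## pad so components touching the frame edge still close
  z <- matrix(0, ny + 2L, nx + 2L)
  z[2:(ny + 1L), 2:(nx + 1L)] <- mask * 1
  ## contourLines expects z[i, j] on x[i], y[j]: pass the transpose so that
  ## i indexes x (columns) and j indexes y (rows)
  cl <- grDevices::contourLines(x = (-1):(nx) , y = (-1):(ny), z = t(z),
                                levels = 0.5)
  if (!length(cl)) stop("mask has no boundary", call. = FALSE)
  len <- vapply(cl, function(c) length(c$x), numeric(1))
  ring <- cl[[which.max(len)]]
  xy <- cbind(ring$x, ring$y) * pixel_size_mm
  vt_contour(xy, closed = TRUE, frame_index = frame_index)
}

#' Apply point edits to an outline
#'
#' Programmatic stand-in for manual outline correction: replaces points at
#' given indices and re-checks that the outline remains simple
#' (non-self-intersecting).
#'
#' @param outline a \code{\link{vt_contour}}.
#' @param edits data.frame with columns \code{index}, \code{x}, \code{y}
#'   (mm); empty or NULL for no-op.
#' @return the corrected \code{vt_contour}.
#' @export
correct_outline <- function(outline, edits = NULL) {
  if (is.null(edits) || nrow(edits) == 0L) return(outline)
  xy <- unclass(outline)
  if (any(edits$index < 1L) || any(edits$index > nrow(xy)))
    stop("edit index out of range", call. = FALSE)
  xy[edits$index, 1] <- edits$x
  xy[edits$index, 2] <- edits$y
  out <- vt_contour(xy, closed = isTRUE(attr(outline, "closed")),
                    frame_index = attr(outline, "frame_index"))
  bad <- find_self_intersection(out)
  if (!is.null(bad))
    stop(sprintf(paste0("edit rejected: outline self-intersects between ",
                        "segments starting at points %d and %d"),
                 bad[1], bad[2]), call. = FALSE)
  out
}

## Brute-force segment intersection scan; returns the first offending
## segment pair or NULL.  Adjacent segments sharing an endpoint are skipped.
find_self_intersection <- function(outline) {
  xy <- unclass(outline)
  if (isTRUE(attr(outline, "closed"))) xy <- rbind(xy, xy[1L, ])
  n <- nrow(xy) - 1L
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n) next
      if (seg_int(xy[i, ], xy[i + 1L, ], xy[j, ], xy[j + 1L, ]))
        return(c(i, j))
    }
  }
  NULL
}

#' Dice overlap coefficient of two masks
#' @param a,b logical masks of equal shape.
#' @return \code{2|A n B| / (|A| + |B|)}.
#' @export
dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Symmetric Hausdorff distance between two outlines
#' @param a,b \code{vt_contour}s (or n x 2 matrices) in mm.
#' @return the largest distance from a point of either outline to the other
#'   outline's points, in mm.
#' @export
hausdorff_distance <- function(a, b) {
  pa <- unclass(a); pb <- unclass(b)
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

#' Head-interior region of an image series
#'
#' Thresholds the temporal mean image (between-class variance
#' maximization), fills enclosed holes — the dark vocal-tract channel is
#' interior to the head — and erodes the result, giving the spatial
#' constraint "the vocal tract lies strictly inside the head".
#'
#' @param series an \code{\link{image_series}}.
#' @param erode_px erosion radius in pixels.
#' @return logical ny x nx mask of the eroded head interior.
#' @export
head_region_mask <- function(series, erode_px = 3L) {
  mu <- apply(series$frames, c(1, 2), mean)
  m <- mu > otsu_threshold(as.vector(mu))
  img <- EBImage::fillHull(ebi_from_mask(m))
  if (erode_px > 0)
    img <- EBImage::erode(img, EBImage::makeBrush(2L * erode_px + 1L,
                                                  "disc"))
  ebi_to_mask(img)
}

#' Segment a registered image series into vocal-tract outlines
#'
#' The full per-series segmentation stage: spatially constrained candidate
#' localization by temporal variance (constrained to the head interior,
#' excluding static structures, widened analyst-style by closing, hole
#' filling and dilation), then per-frame tissue classification and outline
#' extraction.
#'
#' @param series a registered \code{\link{image_series}}.
#' @param quantile,closing_px,fill_holes,dilate_px candidate-mask
#'   parameters, see \code{\link{high_variance_mask}}; the defaults widen
#'   the raw variance mask into a candidate region covering stable air.
#' @param static_mask optional static-structure \code{\link{pixel_mask}}
#'   excluded from the candidate region.
#' @param truth optional list of ground-truth air masks (or outlines) for
#'   per-frame Dice logging.
#' @return list with \code{outlines} (list of \code{vt_contour}),
#'   \code{candidates} (the \code{pixel_mask} used), \code{air_masks}
#'   (list of logical masks), \code{quality} (per-frame data.frame with
#'   threshold, low-contrast flag and Dice where truth was given).
#' @export
segment_series <- function(series, quantile = 0.85, closing_px = 6L,
                           fill_holes = TRUE, dilate_px = 4L,
                           static_mask = NULL, truth = NULL) {
  head <- head_region_mask(series)
  exclude <- !head
  if (!is.null(static_mask)) exclude <- exclude | unclass(static_mask)
  ## variance evidence: pixels that alternate between air and tissue
  varmask <- high_variance_mask(series, quantile, closing_px = 1L,
                                exclude = exclude)
  ## stable-air evidence: pixels dark in the temporal mean (the always-air
  ## channel core never brightens); together these emulate the analyst's
  ## "may sometimes contain vocal tract" mask
  mu <- apply(series$frames, c(1, 2), mean)
  dark <- head & !exclude & (mu < otsu_threshold(mu[head]))
  m <- ebi_from_mask(unclass(varmask) | dark)
  if (closing_px > 0)
    m <- EBImage::closing(m, EBImage::makeBrush(2L * closing_px + 1L,
                                                "disc"))
  lab <- EBImage::bwlabel(m)
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(tab))
    m <- EBImage::Image((EBImage::imageData(lab) == which.max(tab)) * 1)
  if (fill_holes) m <- EBImage::fillHull(m)
  if (dilate_px > 0)
    m <- EBImage::dilate(m, EBImage::makeBrush(2L * dilate_px + 1L, "disc"))
  cand <- pixel_mask(ebi_to_mask(m), kind = "labile_candidates")
  nf <- n_frames(series)
  outlines <- vector("list", nf)
  air_masks <- vector("list", nf)
  qual <- vector("list", nf)
  for (i in seq_len(nf)) {
    f <- get_frame(series, i)
    tis <- classify_tissue(f, cand)
    air <- cand & !tis
    lab <- EBImage::bwlabel(ebi_from_mask(air))
    tab <- tabulate(as.integer(EBImage::imageData(lab)))
    comp <- t(EBImage::imageData(lab)) == which.max(tab)
    outlines[[i]] <- mask_outline(comp, series$pixel_size_mm,
                                  series$labels$frame_index[i])
    air_masks[[i]] <- comp
    d <- NA_real_
    if (!is.null(truth)) d <- dice_coefficient(comp, truth[[i]])
    qual[[i]] <- data.frame(frame_index = series$labels$frame_index[i],
                            threshold = attr(tis, "threshold"),
                            low_contrast = attr(tis, "low_contrast"),
                            dice = d)
  }
  list(outlines = outlines, candidates = cand, air_masks = air_masks,
       quality = do.call(rbind, qual))
}
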