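#' Resample an outline to equal arc-length spacing
#'
#' Produces the fixed-length parametrization used by the functional PCA:
#' \code{n_points} samples equally spaced in arc length, start landmark and
#' orientation enforced.  Closed outlines are cut at the anterior-most (lip)
#' boundary point — the vertex with minimal x, ties broken by minimal y —
#' and traversed in the canonical positive orientation; open traces are
#' oriented to start at the endpoint with smaller x and sampled including
#' both endpoints.
#'
#' @param outline a \code{\link{vt_contour}} (closed or open).
#' @param n_points number of output samples (>= 20).
#' @return a \code{vt_contour} with \code{n_points} rows; for closed input
#'   the last point does not repeat the first.
#' @export
resample_contour <- function(outline, n_points = 100L) {
  if (n_points < 20L) stop("n_points must be >= 20", call. = FALSE)
  xy <- unclass(outline)
  closed <- isTRUE(attr(outline, "closed"))
  if (closed) {
    if (contour_signed_area(outline) < 0) xy <- xy[nrow(xy):1, , drop = FALSE]
    start <- which(xy[, 1] == min(xy[, 1]))
    if (length(start) > 1L) start <- start[which.min(xy[start, 2])]
    if (start > 1L) xy <- rbind(xy[start:nrow(xy), , drop = FALSE],
                                xy[seq_len(start - 1L), , drop = FALSE])
    xy <- rbind(xy, xy[1L, ])
  } else {
    if (xy[1L, 1] > xy[nrow(xy), 1]) xy <- xy[nrow(xy):1, , drop = FALSE]
  }
  d <- c(0, cumsum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)))
  L <- d[length(d)]
  if (L <= 0) stop("degenerate (zero-length) outline", call. = FALSE)
  keep <- c(TRUE, diff(d) > 0)
  xy <- xy[keep, , drop = FALSE]; d <- d[keep]
  s <- if (closed) seq(0, L, length.out = n_points + 1L)[-(n_points + 1L)]
       else seq(0, L, length.out = n_points)
  vt_contour(cbind(stats::approx(d, xy[, 1], xout = s)$y,
                   stats::approx(d, xy[, 2], xout = s)$y),
             closed = closed, frame_index = attr(outline, "frame_index"))
}

#' Stack outlines into a curve matrix
#'
#' @param outlines list of \code{vt_contour}s.
#' @param n_points resampling resolution.
#' @return n x 2\code{n_points} matrix; row i is curve i as concatenated
#'   (x(t), y(t)) samples, with a \code{frame_index} attribute vector.
#' @export
curves_matrix <- function(outlines, n_points = 100L) {
  m <- t(vapply(outlines,
                function(o) as.vector(unclass(resample_contour(o, n_points))),
                numeric(2L * n_points)))
  structure(m, frame_index = vapply(outlines,
                                    function(o) attr(o, "frame_index"),
                                    integer(1)))
}

## curve vector (length 2m) -> m x 2 matrix
curve_xy <- function(v) matrix(v, ncol = 2L)

#' Functional principal component analysis of vocal-tract contours
#'
#' Fits a bivariate functional PCA to a set of equal-length parametrized
#' contours.  The two coordinate functions x(t), y(t) of each contour are
#' concatenated into a single functional observation, optionally projected
#' onto a B-spline basis (penalized least squares with a second-difference
#' penalty; the default penalty 0 gives plain least-squares projection), and
#' the principal modes are obtained by exact eigendecomposition of the
#' sample covariance under the uniform discrete inner product — so with
#' smoothing disabled the eigenvalues coincide with those of the discrete
#' covariance matrix of the sampled coordinates.
#'
#' @param curves n x 2m numeric matrix of curves (rows are concatenated
#'   (x, y) samples, as from \code{\link{curves_matrix}}), or a list of
#'   \code{vt_contour}s.
#' @param n_components number of components K to retain.
#' @param basis \code{"none"} (work on the raw sample grid) or
#'   \code{"bspline"} (project each coordinate function onto a B-spline
#'   basis first).
#' @param nbasis number of B-spline basis functions per coordinate.
#' @param lambda roughness penalty on squared second differences of basis
#'   coefficients; 0 disables it.
#' @param n_points resampling resolution when \code{curves} is a list.
#' @param labels optional data.frame (one row per curve) of frame labels
#'   carried into the score table.
#' @return An object of class \code{"vt_fpca"}: list with \code{mean}
#'   (length-2m mean curve), \code{efuns} (2m x K orthonormal
#'   eigenfunctions), \code{evals} (their eigenvalues, mm^2),
#'   \code{all_evals} (full spectrum), \code{prop_var} (variance
#'   proportions), \code{scores} (n x K training scores), \code{n_points},
#'   \code{closed}, \code{basis} description, \code{sign_convention},
#'   \code{labels}.
#' @export
vt_fpca <- function(curves, n_components = 5L,
                    basis = c("bspline", "none"), nbasis = 40L, lambda = 0,
                    n_points = 100L, labels = NULL, closed = TRUE) {
  basis <- match.arg(basis)
  if (is.list(curves) && !is.matrix(curves))
    curves <- curves_matrix(curves, n_points)
  X <- as.matrix(curves)
  n <- nrow(X); m <- ncol(X) / 2L
  if (m != floor(m)) stop("curve matrix must have an even column count",
                          call. = FALSE)
  if (n < n_components + 1L)
    stop("need at least n_components + 1 curves", call. = FALSE)

  smoother <- NULL
  if (basis == "bspline") {
    smoother <- bspline_smoother(m, min(nbasis, m), lambda)
    X <- cbind(X[, 1:m] %*% smoother, X[, (m + 1):(2 * m)] %*% smoother)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc)
  all_evals <- sv$d^2 / (n - 1)
  k <- min(n_components, ncol(sv$v))
  efuns <- sv$v[, seq_len(k), drop = FALSE]
  scores <- Xc %*% efuns
  total <- sum(all_evals)
  structure(list(
    mean = mu, efuns = efuns, evals = all_evals[seq_len(k)],
    all_evals = all_evals,
    prop_var = if (total > 0) all_evals[seq_len(k)] / total
               else rep(0, k),
    scores = scores, n = n, n_points = m,
    closed = closed,
    basis = list(type = basis, nbasis = nbasis, lambda = lambda,
                 smoother = smoother),
    sign_convention = rep("unoriented", k),
    labels = labels, call = match.call()),
    class = "vt_fpca")
}

## Penalized B-spline smoother matrix (m x m): maps sampled values to
## fitted values of a least-squares B-spline fit with second-difference
## coefficient penalty (P-spline).
bspline_smoother <- function(m, nbasis, lambda = 0) {
  t <- seq(0, 1, length.out = m)
  degree <- 3L
  nknots <- nbasis - degree + 1L
  knots <- c(rep(0, degree), seq(0, 1, length.out = nknots),
             rep(1, degree))
  B <- splines::splineDesign(knots, t, ord = degree + 1L)
  D <- diff(diag(nbasis), differences = 2L)
  A <- crossprod(B) + lambda * crossprod(D)
  B %*% solve(A, t(B))
}

#' @export
print.vt_fpca <- function(x, ...) {
  k <- length(x$evals)
  cat(sprintf("Functional PCA of %d contours (%d points each)\n",
              x$n, x$n_points))
  cat(sprintf("  basis: %s%s\n", x$basis$type,
              if (x$basis$type == "bspline")
                sprintf(" (%d fns, lambda = %g)", x$basis$nbasis,
                        x$basis$lambda) else ""))
  cat(sprintf("  %d components, %.1f%% of variance\n", k,
              100 * sum(x$prop_var)))
  invisible(x)
}

#' @export
summary.vt_fpca <- function(object, ...) {
  ve <- variance_explained(object)
  cat(sprintf("Functional PCA: %d curves, %d components\n",
              object$n, length(object$evals)))
  print(ve, row.names = FALSE, digits = 3)
  invisible(ve)
}

#' Per-component variance proportions of a fitted fPCA
#' @param model a \code{\link{vt_fpca}} fit.
#' @return data.frame with \code{component}, \code{eigenvalue},
#'   \code{proportion} and nondecreasing \code{cumulative} columns.
#' @export
variance_explained <- function(model) {
  stopifnot(inherits(model, "vt_fpca"))
  data.frame(component = seq_along(model$evals),
             eigenvalue = model$evals,
             proportion = model$prop_var,
             cumulative = cumsum(model$prop_var))
}

#' Project contours onto fitted components
#'
#' Scores are inner products of the centered (and, if the model smooths,
#' smoothed) curves with the eigenfunctions.
#'
#' @param object a \code{\link{vt_fpca}} fit.
#' @param newdata curve matrix or list of \code{vt_contour}s; omitted for
#'   the training scores.
#' @param labels optional per-curve label data.frame to bind to the scores.
#' @param ... unused.
#' @return data.frame with label columns (if any) and score columns
#'   \code{fPC1..fPCK} in mm.
#' @export
predict.vt_fpca <- function(object, newdata = NULL, labels = NULL, ...) {
  if (is.null(newdata)) {
    sc <- object$scores
    if (is.null(labels)) labels <- object$labels
  } else {
    if (is.list(newdata) && !is.matrix(newdata))
      newdata <- curves_matrix(newdata, object$n_points)
    X <- as.matrix(newdata)
    if (ncol(X) != 2L * object$n_points)
      stop("curve sampling does not match the fitted model", call. = FALSE)
    m <- object$n_points
    if (!is.null(object$basis$smoother))
      X <- cbind(X[, 1:m] %*% object$basis$smoother,
                 X[, (m + 1):(2 * m)] %*% object$basis$smoother)
    sc <- sweep(X, 2L, object$mean) %*% object$efuns
  }
  colnames(sc) <- paste0("fPC", seq_len(ncol(sc)))
  if (!is.null(labels)) cbind(labels, as.data.frame(sc))
  else as.data.frame(sc)
}

#' Score table of outlines under a fitted fPCA
#'
#' Convenience wrapper around \code{\link{predict.vt_fpca}} binding frame
#' labels to component scores.
#'
#' @param model a \code{\link{vt_fpca}} fit.
#' @param outlines list of \code{vt_contour}s (or curve matrix).
#' @param labels data.frame of frame labels, one row per curve.
#' @return data.frame: labels + \code{fPC1..fPCK}.
#' @export
project_scores <- function(model, outlines, labels = NULL) {
  predict(model, newdata = outlines, labels = labels)
}

#' Reconstruct a contour from component scores
#'
#' The companion-app operation: mean shape plus the score-weighted sum of
#' eigenfunctions.
#'
#' @param model a \code{\link{vt_fpca}} fit.
#' @param scores numeric vector of per-component scores (mm); shorter
#'   vectors are zero-padded.
#' @param warn_sd range (in per-component SDs) beyond which a warning is
#'   emitted; reconstruction still proceeds.
#' @return a \code{vt_contour} of the reconstructed shape.
#' @export
reconstruct_shape <- function(model, scores, warn_sd = 3) {
  stopifnot(inherits(model, "vt_fpca"))
  k <- ncol(model$efuns)
  s <- rep(0, k)
  s[seq_along(scores)] <- scores
  sd <- sqrt(pmax(model$evals, .Machine$double.eps))
  if (any(abs(s) > warn_sd * sd))
    warning("scores exceed ", warn_sd, " SD of the fitted components",
            call. = FALSE)
  v <- model$mean + as.vector(model$efuns %*% s)
  vt_contour(curve_xy(v), closed = model$closed)
}

#' @export
fitted.vt_fpca <- function(object, ...) {
  sweep(object$scores %*% t(object$efuns), 2L, -object$mean)
}

#' @export
plot.vt_fpca <- function(x, components = seq_along(x$evals), sd_range = 2,
                         ...) {
  op <- graphics::par(mfrow = c(1, length(components) + 1L))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(seq_along(x$all_evals[1:min(10, length(x$all_evals))]),
                 x$all_evals[1:min(10, length(x$all_evals))] /
                   sum(x$all_evals),
                 type = "b", xlab = "component", ylab = "proportion",
                 main = "scree")
  for (k in components) {
    mu <- curve_xy(x$mean)
    lo <- curve_xy(x$mean - sd_range * sqrt(x$evals[k]) * x$efuns[, k])
    hi <- curve_xy(x$mean + sd_range * sqrt(x$evals[k]) * x$efuns[, k])
    graphics::plot(mu, type = "l", asp = 1, ylim = rev(range(mu[, 2])),
                   xlab = "x (mm)", ylab = "y (mm)",
                   main = sprintf("fPC%d (%.1f%%)", k, 100 * x$prop_var[k]))
    graphics::lines(lo, col = "purple")
    graphics::lines(hi, col = "orange")
  }
  invisible(x)
}

#' Fix component signs against reference deformations
#'
#' Eigenfunction signs are arbitrary; this orients each requested component
#' so that its inner product with a reference deformation curve is positive
#' (e.g. "positive length-component score = raised larynx = smaller
#' tract"), flipping stored training scores consistently.
#'
#' @param model a \code{\link{vt_fpca}} fit.
#' @param reference 2m x K matrix (or list of length-2m vectors) of
#'   reference deformations, one per component to orient; \code{NA} columns
#'   are skipped.
#' @return the model with oriented eigenfunctions, scores and an updated
#'   \code{sign_convention} record.
#' @export
orient_components <- function(model, reference) {
  stopifnot(inherits(model, "vt_fpca"))
  if (is.list(reference)) reference <- do.call(cbind, reference)
  reference <- as.matrix(reference)
  k <- min(ncol(reference), ncol(model$efuns))
  for (j in seq_len(k)) {
    r <- reference[, j]
    if (all(is.na(r))) next
    ip <- sum(model$efuns[, j] * r)
    if (ip == 0) {
      warning("component ", j, " is orientation-ambiguous ",
              "(zero inner product with its reference)", call. = FALSE)
      next
    }
    if (ip < 0) {
      model$efuns[, j] <- -model$efuns[, j]
      model$scores[, j] <- -model$scores[, j]
      model$sign_convention[j] <- "flipped to match reference"
    } else model$sign_convention[j] <- "matches reference"
  }
  model
}

#' Canonical deformation curves of the phantom generator
#'
#' Finite-difference derivatives of the resampled template contour with
#' respect to each shape parameter, used as orientation references and to
#' identify which fitted component tracks vocal-tract length.
#'
#' @param n_points resampling resolution (must match the fitted model).
#' @param eps finite-difference step.
#' @return 2\code{n_points} x 5 matrix of unit-norm deformations, columns
#'   \code{tongue_position}, \code{larynx_height} (positive = raised larynx,
#'   shorter tract), \code{body_scale}, \code{tongue_shape},
#'   \code{curvature}.
#' @export
canonical_deformations <- function(n_points = 100L, eps = 0.02) {
  base <- c(0, 0, 1, 0, 0)
  flat <- function(p)
    as.vector(unclass(resample_contour(
      make_vocal_tract_contour(shape_params(p[1], p[2], p[3], p[4], p[5])),
      n_points)))
  f0 <- flat(base)
  d <- vapply(1:5, function(k) {
    p <- base; p[k] <- p[k] + eps
    v <- (flat(p) - f0) / eps
    v / sqrt(sum(v^2))
  }, numeric(2L * n_points))
  colnames(d) <- c("tongue_position", "larynx_height", "body_scale",
                   "tongue_shape", "curvature")
  d
}

#' Identify the component most aligned with a reference deformation
#'
#' @param model a \code{\link{vt_fpca}} fit.
#' @param reference length-2m deformation curve (e.g. a column of
#'   \code{\link{canonical_deformations}}).
#' @return integer component index with the largest absolute cosine
#'   similarity to the reference.
#' @export
match_component <- function(model, reference) {
  stopifnot(inherits(model, "vt_fpca"))
  r <- reference / sqrt(sum(reference^2))
  which.max(abs(as.vector(crossprod(model$efuns, r))))
}
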