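test_that("equal-arc resampling fixes spacing, start and orientation", {
  ## unit circle: constant speed
  th <- seq(0, 2 * pi, length.out = 4000)[-4000]
  circ <- vt_contour(cbind(cos(th), sin(th)), closed = TRUE)
  r <- resample_contour(circ, 100L)
  gaps <- sqrt(diff(rbind(unclass(r), unclass(r)[1, ])[, 1])^2 +
                 diff(rbind(unclass(r), unclass(r)[1, ])[, 2])^2)
  expect_lt(diff(range(gaps)), 1e-6)
  ## an exactly equally spaced closed curve is a fixed point
  th100 <- pi + seq(0, 2 * pi, length.out = 101)[-101]
  ex <- vt_contour(cbind(cos(th100), sin(th100)), closed = TRUE)
  r2 <- resample_contour(ex, 100L)
  expect_lt(max(abs(unclass(r2) - unclass(ex))), 1e-9)
  ## round trip through doubled resolution
  o <- make_vocal_tract_contour(shape_params(0.3, -0.2, 1, 0.1, 0))
  a <- resample_contour(o, 100L)
  b <- resample_contour(resample_contour(o, 200L), 100L)
  expect_lt(max(abs(unclass(a) - unclass(b))), 0.1)
  expect_error(resample_contour(vt_contour(matrix(1, 25, 2), closed = FALSE)),
               "degenerate")
})

test_that("identical curves give zero eigenvalues and scores", {
  base <- resample_contour(make_vocal_tract_contour(shape_params()), 60L)
  X <- matrix(rep(as.vector(unclass(base)), 10), nrow = 10, byrow = TRUE)
  m <- vt_fpca(X, 3, basis = "none")
  expect_true(all(m$evals < 1e-20))
  expect_true(all(abs(m$scores) < 1e-8))
})

test_that("a single planted mode is recovered almost perfectly", {
  set.seed(5)
  n <- 120L; npts <- 50L
  mu <- as.vector(unclass(resample_contour(
    make_vocal_tract_contour(shape_params()), npts)))
  phi <- sin(seq(0, 4 * pi, length.out = 2 * npts))
  phi <- phi / sqrt(sum(phi^2))
  a <- rnorm(n)
  X <- outer(a, phi) + matrix(mu, n, 2 * npts, byrow = TRUE)
  m <- vt_fpca(X, 3, basis = "none")
  expect_gte(m$prop_var[1], 0.999)
  expect_gte(abs(cor(m$scores[, 1], a)), 0.999)
})

test_that("eigenvalues equal the brute-force covariance spectrum", {
  pm <- plant_shape_modes(n = 60L, n_points = 40L, seed = 3L)
  m <- vt_fpca(pm$curves, 5, basis = "none")
  oracle <- eigen(cov(pm$curves), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(abs(m$evals - oracle[1:5]) / oracle[1:5]), 1e-8)
})

test_that("projection satisfies the PCA identities", {
  pm <- plant_shape_modes(n = 80L, n_points = 40L, seed = 4L)
  m <- vt_fpca(pm$curves, 4, basis = "none")
  ## the mean curve scores zero
  s0 <- predict(m, matrix(m$mean, 1))
  expect_lt(max(abs(s0)), 1e-6)
  ## mean + 2 phi_1 scores exactly (2, 0, 0, ...)
  s2 <- predict(m, matrix(m$mean + 2 * m$efuns[, 1], 1))
  expect_equal(as.numeric(s2[1, 1]), 2, tolerance = 1e-6)
  expect_lt(max(abs(s2[1, -1])), 1e-6)
  ## training score variances equal the eigenvalues
  v <- apply(predict(m), 2, function(x) sum((x - mean(x))^2) / (m$n - 1))
  expect_equal(unname(v), m$evals, tolerance = 1e-6)
  expect_error(predict(m, matrix(0, 1, 10)), "sampling")
})

test_that("reconstruction inverts projection", {
  pm <- plant_shape_modes(n = 60L, n_points = 40L, seed = 6L)
  m <- vt_fpca(pm$curves, 5, basis = "none")
  ## zero scores give the mean curve
  expect_equal(as.vector(unclass(reconstruct_shape(m, 0))), unname(m$mean),
               tolerance = 1e-12)
  ## full-rank reconstruction of a curve lying in the mode span
  full <- vt_fpca(pm$curves, 59L, basis = "none")
  x <- pm$curves[7, ]
  sc <- as.numeric(predict(full, matrix(x, 1)))
  rec <- suppressWarnings(reconstruct_shape(full, sc))
  expect_lt(max(abs(as.vector(unclass(rec)) - x)), 1e-6)
  ## two-mode data is exact at K = 5 already
  two <- plant_shape_modes(n = 40L,
                           shares = c(1e-12, 0.6, 1e-12, 0.4, 1e-12),
                           n_points = 40L, seed = 7L)
  m2 <- vt_fpca(two$curves, 5, basis = "none")
  x2 <- two$curves[3, ]
  rec2 <- suppressWarnings(
    reconstruct_shape(m2, as.numeric(predict(m2, matrix(x2, 1)))))
  expect_lt(max(abs(as.vector(unclass(rec2)) - x2)), 2e-3)
})

test_that("component orientation is involutive and reference-driven", {
  pm <- plant_shape_modes(n = 60L, n_points = 40L, seed = 8L)
  m <- vt_fpca(pm$curves, 3, basis = "none")
  ref <- m$efuns                      # already aligned references
  m1 <- orient_components(m, ref)
  expect_identical(m1$efuns, m$efuns)
  ## flip then re-orient restores the original
  mf <- m; mf$efuns[, 2] <- -mf$efuns[, 2]; mf$scores[, 2] <- -mf$scores[, 2]
  m2 <- orient_components(mf, ref)
  expect_equal(m2$efuns, m$efuns)
  expect_equal(m2$scores, m$scores)
  expect_warning(orient_components(m, cbind(rep(0, 80))), "ambiguous")
})

test_that("variance proportions report planted shares and cumulate", {
  two <- plant_shape_modes(n = 500L,
                           shares = c(1e-9, 0.8, 1e-9, 0.2, 1e-9),
                           n_points = 60L, seed = 9L)
  m <- vt_fpca(two$curves, 5, basis = "none")
  ve <- variance_explained(m)
  expect_equal(ve$proportion[1:2], c(0.8, 0.2), tolerance = 0.02)
  expect_equal(ve$cumulative, cumsum(ve$proportion), tolerance = 1e-12)
  expect_true(all(diff(ve$cumulative) >= 0))
})

test_that("translation moves only the mean; scaling acts quadratically", {
  pm <- plant_shape_modes(n = 60L, n_points = 40L, seed = 10L)
  m0 <- vt_fpca(pm$curves, 4, basis = "none")
  mt <- vt_fpca(pm$curves + 12.5, 4, basis = "none")
  expect_equal(mt$mean, m0$mean + 12.5, tolerance = 1e-9)
  expect_lt(max(abs(abs(mt$efuns) - abs(m0$efuns))), 1e-8)
  expect_equal(mt$evals, m0$evals, tolerance = 1e-8)
  expect_lt(max(abs(mt$scores - m0$scores)), 1e-6)
  ms <- vt_fpca(3 * pm$curves, 4, basis = "none")
  expect_equal(ms$evals, 9 * m0$evals, tolerance = 1e-8)
  expect_equal(ms$prop_var, m0$prop_var, tolerance = 1e-10)
  expect_lt(max(abs(abs(ms$scores) - 3 * abs(m0$scores))), 1e-6)
})

test_that("oriented length scores are higher when imitating small targets", {
  ses <- fix_session()
  m <- vt_fpca(ses$seg$outlines, 5)
  defs <- canonical_deformations(100L)
  k <- match_component(m, defs[, "larynx_height"])
  ref <- matrix(NA_real_, 200, ncol(m$efuns))
  ref[, k] <- defs[, "larynx_height"]
  m <- orient_components(m, ref)
  sc <- predict(m, labels = ses$registered$series$labels)
  col <- paste0("fPC", k)
  expect_gt(median(sc[[col]][sc$vt_condition == "small"]),
            median(sc[[col]][sc$vt_condition == "large"]))
})

test_that("five planted modes are recovered with the paper-scale shares", {
  pm <- plant_shape_modes(n = 300L, seed = 13L)
  m <- vt_fpca(pm$curves, 5)
  expect_lt(max(abs(m$prop_var - pm$shares)), 0.05)
  cm <- cor(as.matrix(predict(m)), pm$params)
  perm <- apply(abs(cm), 1, which.max)
  expect_equal(sort(unname(perm)), 1:5)
  expect_gte(min(abs(cm[cbind(1:5, perm)])), 0.9)
})
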