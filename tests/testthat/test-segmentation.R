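test_that("identity registration is recovered for identical frames", {
  f <- fix_reference()
  t <- estimate_rigid_transform(f, f, fix_static_mask())
  expect_lt(abs(t$rotation_deg), 0.05)
  expect_lt(abs(t$tx_mm), 0.05)
  expect_lt(abs(t$ty_mm), 0.05)
})

test_that("planted rigid motion is recovered within half a degree and mm", {
  outl <- make_vocal_tract_contour(shape_params())
  ref <- fix_reference(); sm <- fix_static_mask()
  motion <- rigid_transform(3, 2, -1)
  fm <- render_frame(outl, motion)
  est <- estimate_rigid_transform(fm, ref, sm)
  tru <- rigid_invert(motion)
  expect_lt(abs(est$rotation_deg - tru$rotation_deg), 0.5)
  expect_lt(abs(est$tx_mm - tru$tx_mm), 0.5)
  expect_lt(abs(est$ty_mm - tru$ty_mm), 0.5)
})

test_that("labile displacement does not bias the static-structure estimate", {
  ref <- fix_reference(); sm <- fix_static_mask()
  motion <- rigid_transform(3, 2, -1)
  ## same head pose, larynx additionally lowered by ~10 mm (labile change)
  moved <- make_vocal_tract_contour(shape_params(larynx_height = -0.67))
  fm <- render_frame(moved, motion)
  est <- estimate_rigid_transform(fm, ref, sm)
  tru <- rigid_invert(motion)
  expect_lt(abs(est$rotation_deg - tru$rotation_deg), 0.5)
  expect_lt(abs(est$tx_mm - tru$tx_mm), 0.5)
  expect_lt(abs(est$ty_mm - tru$ty_mm), 0.5)
})

test_that("registration is equivariant to pre-rotation", {
  ref <- fix_reference(); sm <- fix_static_mask()
  outl <- make_vocal_tract_contour(shape_params())
  for (delta in c(-6, 4)) {
    fm <- render_frame(outl, rigid_transform(delta, 0, 0))
    est <- estimate_rigid_transform(fm, ref, sm)
    expect_lt(abs(est$rotation_deg - (-delta)), 0.5)
  }
})

test_that("a flat masked region cannot be registered", {
  f <- fix_reference()
  flat <- pixel_mask(matrix(c(rep(TRUE, 40), rep(FALSE, 9640)), 110, 88))
  expect_error(estimate_rigid_transform(f, f, flat), "flat")
})

test_that("apply_transform: identity, impulse shift, and round trip", {
  f <- fix_reference()
  expect_identical(apply_transform(f, rigid_transform())$intensities,
                   f$intensities)
  ## impulse moved exactly one pixel column by a 2.5 mm translation
  imp <- matrix(0, 110, 88); imp[60, 40] <- 1
  fi <- image_frame(imp, 2.5)
  sh <- apply_transform(fi, rigid_transform(0, 2.5, 0))$intensities
  expect_equal(sh[60, 41], 1, tolerance = 1e-9)
  expect_equal(sum(sh), 1, tolerance = 1e-9)
  ## round trip on a smooth image
  g <- pixel_grid(render_config())
  smooth <- image_frame(200 * exp(-((g$x - 110)^2 + (g$y - 136)^2) / 3000),
                        2.5)
  t <- rigid_transform(5, 3, -2)
  back <- apply_transform(apply_transform(smooth, t), rigid_invert(t))
  interior <- g$x > 30 & g$x < 185 & g$y > 30 & g$y < 240
  err <- mean(abs(back$intensities[interior] -
                    smooth$intensities[interior]))
  expect_lt(err, 0.01 * 200)
})

test_that("temporal variance localizes alternating vocal-tract pixels", {
  ses <- fix_session()
  series <- ses$registered$series
  ## ground-truth alternating set: air in some frame, tissue in another
  gt <- sapply(ses$raw$truth$outlines,
               function(o) as.vector(unclass(rasterize_outline(o))))
  air_any <- matrix(rowSums(gt) > 0, 110, 88)
  air_all <- matrix(rowSums(gt) == ncol(gt), 110, 88)
  altern <- air_any & !air_all
  m <- high_variance_mask(series, 0.85,
                          exclude = !head_region_mask(series) |
                            unclass(fix_static_mask()))
  expect_gte(mean(m[altern]), 0.95)
  ## monotonicity in the quantile
  m99 <- high_variance_mask(series, 0.99, closing_px = 0L)
  m90 <- high_variance_mask(series, 0.90, closing_px = 0L)
  expect_lte(sum(m99), sum(m90))
})

test_that("a constant series yields an empty variance mask", {
  arr <- array(7, c(20, 20, 4))
  s <- image_series(arr)
  expect_equal(sum(high_variance_mask(s, 0.85)), 0)
  expect_error(high_variance_mask(image_series(array(0, c(5, 5, 1)))),
               "at least 2 frames")
})

test_that("tissue classification is exact on noiseless frames", {
  ses <- fix_session()
  f <- get_frame(ses$registered$series, 1L)
  cand <- ses$seg$candidates
  tis <- classify_tissue(f, cand)
  expect_false(attr(tis, "low_contrast"))
  ## inverting intensities and labels gives the same boundary (up to
  ## histogram-bin edge effects on interpolated edge pixels)
  fi <- image_frame(255 - f$intensities, f$pixel_size_mm)
  tis_i <- classify_tissue(fi, cand)
  agree <- mean((unclass(tis_i) == unclass(cand & !tis))[unclass(cand)])
  expect_gte(agree, 1 - 2 / sum(cand))
  expect_error(classify_tissue(f, pixel_mask(matrix(FALSE, 110, 88))),
               "empty")
})

test_that("noisy classification stays above 98% pixel accuracy", {
  cfg <- render_config()
  outl <- make_vocal_tract_contour(shape_params())
  gt <- unclass(rasterize_outline(outl, cfg))
  cand <- unclass(fix_session()$seg$candidates)
  acc <- vapply(1:30, function(s) {
    f <- render_frame(outl, noise_sd = 10, seed = s)
    tis <- classify_tissue(f, pixel_mask(cand))
    mean((unclass(cand & !tis) == (gt & cand))[cand])
  }, numeric(1))
  expect_gte(mean(acc), 0.98)
})

test_that("disk boundary length and sub-pixel tracing are accurate", {
  m <- matrix(FALSE, 60, 60)
  g <- expand.grid(r = 1:60, c = 1:60)
  m[as.matrix(g[ (g$r - 30)^2 + (g$c - 30)^2 <= 10^2, ])] <- TRUE
  o <- mask_outline(m, pixel_size_mm = 1)
  expect_equal(contour_length(o), 2 * pi * 10, tolerance = 0.02 * 2 * pi * 10)
})

test_that("small artifact components are ignored by outline extraction", {
  cand <- matrix(FALSE, 40, 40); cand[5:35, 5:35] <- TRUE
  tissue <- cand
  tissue[10:30, 10:20] <- FALSE       # main air region (231 px)
  tissue[6:7, 30:32] <- FALSE         # artifact (6 px)
  o <- extract_outline(pixel_mask(tissue, "tissue"), pixel_mask(cand),
                       pixel_size_mm = 1)
  xy <- unclass(o)
  expect_true(all(xy[, 1] >= 8.5 & xy[, 1] <= 21.5))  # cols of main region
  expect_error(extract_outline(pixel_mask(cand, "tissue"),
                               pixel_mask(cand)),
               "no air")
})

test_that("outline correction applies edits and rejects intersections", {
  o <- resample_contour(make_vocal_tract_contour(shape_params()), 80L)
  expect_identical(correct_outline(o, NULL), o)
  xy <- unclass(o)
  same <- data.frame(index = 5L, x = xy[5, 1], y = xy[5, 2])
  expect_identical(unclass(correct_outline(o, same)), xy)
  ## plant a 5 mm spike, then repair it
  spiked <- xy; spiked[40, ] <- spiked[40, ] + c(5, 0)
  so <- vt_contour(spiked, closed = TRUE)
  h0 <- hausdorff_distance(so, o)
  fixed <- correct_outline(so, data.frame(index = 40L, x = xy[40, 1],
                                          y = xy[40, 2]))
  expect_lt(hausdorff_distance(fixed, o), h0)
  ## an edit that makes the polygon cross itself is rejected
  bad <- data.frame(index = 10L, x = xy[30, 1], y = xy[30, 2] + 30)
  expect_error(correct_outline(o, bad), "self-intersect")
  expect_error(correct_outline(o, data.frame(index = 1e4, x = 0, y = 0)),
               "out of range")
})

test_that("noiseless end-to-end segmentation matches ground truth", {
  ses <- fix_session()
  n <- length(ses$seg$outlines)
  dice <- vapply(seq_len(n), function(i)
    dice_coefficient(ses$seg$air_masks[[i]],
                     unclass(rasterize_outline(ses$raw$truth$outlines[[i]]))),
    numeric(1))
  hd <- vapply(seq_len(n), function(i)
    hausdorff_distance(ses$seg$outlines[[i]], ses$raw$truth$outlines[[i]]),
    numeric(1))
  expect_gte(min(dice), 0.95)
  expect_lte(max(hd), 2.6)   # about one 2.5 mm pixel, incl. residual motion
})

test_that("outline areas are invariant to a global series translation", {
  ses <- fix_session()
  raw <- ses$raw$series
  shifted <- raw
  for (i in seq_len(n_frames(raw)))
    shifted$frames[, , i] <- apply_transform(get_frame(raw, i),
                                             rigid_transform(0, 5, -5)
                                             )$intensities
  reg <- register_series(shifted, fix_reference(), fix_static_mask())
  seg <- segment_series(reg$series, static_mask = fix_static_mask())
  a0 <- vapply(ses$seg$outlines, contour_signed_area, numeric(1))
  a1 <- vapply(seg$outlines, contour_signed_area, numeric(1))
  expect_lt(max(abs(a1 - a0) / a0), 0.02)
})
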