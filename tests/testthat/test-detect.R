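# Ridge filtering, apex detection, path tracing and width measurement,
# validated against phantom ground truth.

test_that("ridge map: degenerate input, centreline response, orientation
           accuracy and rotation equivariance", {
  flat <- matrix(0.5, 60, 80)
  r0 <- ridge_map(flat, c(8, 12))
  expect_true(all(r0$response == 0))

  sc <- phantom_scene(n = 1, seed = 3, noise_sd = 0, tortuosity = 0,
                      texture_amplitude = 0, width = 12)
  limb <- sc$truth$paths[[1]]$points
  limb <- limb[limb$arc_from_apex > 40, ]
  on_ridge <- interp_bilinear(sc$ridge$response, limb$x, limb$y)
  bgm <- median(sc$ridge$response)
  expect_true(all(on_ridge > 5 * max(bgm, 1e-12)))
  # orientation on straight limbs within 5 degrees of the known axis
  ori <- interp_bilinear(sc$ridge$orientation, limb$x, limb$y)
  axis <- sc$truth$principal_orientations[1]
  dd <- abs(((ori - axis) + pi / 2) %% pi - pi / 2)
  expect_lt(max(dd), 5 * pi / 180)
  # circular SD of limb orientation estimates is small
  expect_gte(circular_dispersion(ori), cos(2 * 5 * pi / 180))

  # rotating the image by 90 degrees rotates the orientation map by 90
  # degrees mod pi: rot[x, H + 1 - y] = img[y, x], directions gain pi/2
  img <- sc$mosaic$image
  rot <- t(img)[, rev(seq_len(nrow(img)))]
  rr <- ridge_map(rot, c(8, 12, 16))
  strong <- sc$ridge$response > 0.5 * max(sc$ridge$response)
  idx <- which(strong, arr.ind = TRUE)[seq(1, sum(strong), by = 37), ,
                                       drop = FALSE]
  worst <- 0
  for (k in seq_len(nrow(idx))) {
    y <- idx[k, 1]; x <- idx[k, 2]
    o1 <- sc$ridge$orientation[y, x]
    o2 <- rr$orientation[x, nrow(img) - y + 1]
    d <- abs((o2 - o1 - pi / 2) %% pi)
    worst <- max(worst, min(d, pi - d))
  }
  expect_lt(worst, 0.05)
})

test_that("apex detection: counts, localisation, merging and ordering", {
  expect_identical(nrow(detect_apices(ridge_map(matrix(0.5, 50, 50), 12))),
                   0L)
  sc <- phantom_scene(n = 8, seed = 11, noise_sd = 0, tortuosity = 0.1)
  ap <- detect_apices(sc$ridge)
  expect_identical(nrow(ap), 8L)
  expect_true(all(diff(ap$x) > 0))   # sorted left to right
  err <- sqrt((ap$x - sc$truth$apices[, 1])^2 +
                (ap$y - sc$truth$apices[, 2])^2)
  expect_lt(max(err), 10)

  # two capillaries closer than the merge radius collapse to one detection
  sc2 <- phantom_scene(n = 2, seed = 5, spacing = 26, noise_sd = 0,
                       tortuosity = 0, derangement_spread = 0,
                       position_jitter_um = c(2, 2))
  ap2 <- detect_apices(sc2$ridge, min_separation_um = 60)
  expect_identical(nrow(ap2), 1L)
})

test_that("path tracing: full limbs on clean tubes, truncation, determinism,
           off-ridge error", {
  sc <- phantom_scene(n = 1, seed = 3, noise_sd = 0, tortuosity = 0,
                      texture_amplitude = 0)
  ap <- detect_apices(sc$ridge)
  p <- trace_path(sc$ridge, c(ap$x[1], ap$y[1]))
  expect_gte(min(p$limb_arc_lengths), 99)
  expect_lte(max(p$limb_arc_lengths), 100 + 1.5)
  # ~1 um arc-length sampling: two 100 um limbs plus the apex sample
  expect_gt(nrow(p$points), 190)
  expect_true(all(p$points$orientation >= 0 & p$points$orientation < pi))
  ai <- p$apex_index
  expect_equal(c(p$points$x[ai], p$points$y[ai]), p$apex_xy)
  p2 <- trace_path(sc$ridge, c(ap$x[1], ap$y[1]))
  expect_identical(p, p2)

  # a short vessel truncates before the 100 um limit
  scs <- phantom_scene(n = 1, seed = 3, noise_sd = 0, tortuosity = 0,
                       texture_amplitude = 0, limb_length_um = 45)
  aps <- detect_apices(scs$ridge)
  ps <- trace_path(scs$ridge, c(aps$x[1], aps$y[1]))
  expect_lt(max(ps$limb_arc_lengths), 95)

  expect_error(trace_path(sc$ridge, c(3, 3)),
               class = "nailfold_trace_error")
})

test_that("width measurement matches the renderer's FWHM definition", {
  sc <- phantom_scene(n = 1, seed = 3, noise_sd = 0, tortuosity = 0,
                      texture_amplitude = 0, width = 12)
  ap <- detect_apices(sc$ridge)
  p <- measure_widths(sc$mosaic, trace_path(sc$ridge, c(ap$x[1], ap$y[1])))
  w <- p$points$width_um[p$points$measurable]
  expect_gt(mean(p$points$measurable), 0.9)
  expect_true(all(abs(w - 12) < 1.5))
  expect_lt(abs(mean(w) - 12), 1)

  # realistic 11.8 um capillary: mean path width within 1 um
  sc2 <- phantom_scene(n = 1, seed = 8, noise_sd = 0.01, width = 11.8,
                       tortuosity = 0.15)
  ap2 <- detect_apices(sc2$ridge)
  p2 <- measure_widths(sc2$mosaic,
                       trace_path(sc2$ridge, c(ap2$x[1], ap2$y[1])))
  expect_lt(abs(mean(p2$points$width_um[p2$points$measurable]) - 11.8), 1)
})

test_that("width measurement flags truncated profiles and fails when most
           points are unmeasurable", {
  sc <- phantom_scene(n = 1, seed = 3, noise_sd = 0, tortuosity = 0,
                      texture_amplitude = 0)
  ap <- detect_apices(sc$ridge)
  p <- trace_path(sc$ridge, c(ap$x[1], ap$y[1]))
  # points whose perpendicular profile leaves the image are flagged and
  # excluded while the rest of the path stays measurable
  p_edge <- p
  k_edge <- 1:5
  p_edge$points$x[k_edge] <- 2
  p_shift <- measure_widths(sc$mosaic, p_edge)
  expect_true(all(!p_shift$points$measurable[k_edge]))
  expect_true(all(is.na(p_shift$points$width_um[k_edge])))
  expect_gt(mean(p_shift$points$measurable), 0.9)

  # a path fully outside any measurable profile support errors
  p_bad <- p
  p_bad$points$x <- rep(1, nrow(p$points))
  expect_error(measure_widths(sc$mosaic, p_bad),
               class = "nailfold_width_error")
})
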