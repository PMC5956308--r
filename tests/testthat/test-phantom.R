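# The software phantom: hairpin geometry, rendering, video advection and
# overlapping-tile generation, all against known ground truth.

test_that("hairpin path: straight limbs align with the principal axis", {
  p <- make_capillary_path(c(100, 150), pi / 2, 12, 100, tortuosity = 0)
  limb <- p$points[abs(p$points$arc_from_apex) > 40, ]
  expect_true(all(abs(limb$orientation - pi / 2) < 1e-9))
  expect_equal(p$apex_xy, c(100, 150), tolerance = 1e-9)
  expect_equal(unname(p$limb_arc_lengths), c(100, 100))
  # apex is a member of the path points
  ai <- p$apex_index
  expect_equal(c(p$points$x[ai], p$points$y[ai]), p$apex_xy,
               tolerance = 1e-9)
  # oblique axis: limb orientations equal the axis mod pi
  p2 <- make_capillary_path(c(100, 150), 1.2, 12, 100, tortuosity = 0)
  limb2 <- p2$points[abs(p2$points$arc_from_apex) > 40, ]
  expect_true(all(abs(limb2$orientation - 1.2) < 1e-9))
})

test_that("hairpin path: tortuosity-free shape score away from the turn is
           near 1 and generation is deterministic", {
  p <- make_capillary_path(c(100, 150), pi / 2, 12, 100, tortuosity = 0)
  limb_or <- p$points$orientation[abs(p$points$arc_from_apex) > 15]
  expect_gte(circular_dispersion(limb_or), 0.9)
  a <- with_seed(5, make_capillary_path(c(0, 0), pi / 2, 12, 100, 0.3))
  b <- with_seed(5, make_capillary_path(c(0, 0), pi / 2, 12, 100, 0.3))
  expect_identical(a, b)
  expect_error(make_capillary_path(c(0, 0), pi / 2, -1, 100),
               class = "nailfold_invalid_parameter")
  expect_error(make_capillary_path(c(0, 0), pi / 2, 12, 0),
               class = "nailfold_invalid_parameter")
})

test_that("phantom truth: per-capillary lists, density convention, scale
           consistency", {
  spec <- phantom_spec(n_capillaries = 5, seed = 3, frame_shape = NULL)
  tr <- phantom_truth(spec)
  expect_length(tr$paths, 5)
  expect_length(tr$principal_orientations, 5)
  expect_length(tr$velocities_mm_s, 5)
  expect_equal(nrow(tr$apices), 5)
  span_mm <- diff(range(tr$apices[, 1])) / 1000
  expect_equal(tr$density_truth, 5 / span_mm)

  # halving the pixel scale and doubling the frame leaves um truths unchanged
  s1 <- phantom_spec(n_capillaries = 3, seed = 9, pixel_scale_um = 1,
                     frame_shape = c(480, 640))
  s2 <- phantom_spec(n_capillaries = 3, seed = 9, pixel_scale_um = 0.5,
                     frame_shape = c(960, 1280))
  t1 <- phantom_truth(s1); t2 <- phantom_truth(s2)
  expect_equal(t1$apices, t2$apices, tolerance = 1e-12)
  expect_equal(t1$paths[[2]]$points$x, t2$paths[[2]]$points$x,
               tolerance = 1e-12)
  expect_equal(t1$density_truth, t2$density_truth, tolerance = 1e-12)
})

test_that("ground-truth self-consistency: summaries on truth geometry
           reproduce the stored truth", {
  spec <- phantom_spec(n_capillaries = 6, seed = 21, frame_shape = NULL,
                       width_um = c(10, 12, 14))
  tr <- phantom_truth(spec)
  caps <- lapply(seq_along(tr$paths), function(i) {
    summarize_capillary(tr$paths[[i]], capillary_id = i)
  })
  nm <- summarize_nailfold(caps, apices_x_um = tr$apices[, 1])
  expect_identical(nm$density, tr$density_truth)
  expect_equal(nm$mean_width, mean(tr$widths_um), tolerance = 1e-12)
  expect_equal(vapply(caps, `[[`, 0, "principal_orientation"),
               tr$principal_orientations, tolerance = 1e-12)
  expect_equal(nm$derangement,
               circular_dispersion(tr$principal_orientations),
               tolerance = 1e-12)
})

test_that("rendered mosaic: centreline minima, FWHM width, determinism,
           degenerate cases", {
  spec <- phantom_spec(n_capillaries = 1, width_um = 12, tortuosity = 0,
                       derangement_spread = 0, position_jitter_um = c(0, 0),
                       noise_sd = 0, texture_amplitude = 0,
                       frame_shape = c(300, 240), apex_y_um = 100, seed = 2)
  tr <- phantom_truth(spec)
  m <- render_mosaic(spec, tr)
  expect_identical(dim(m$image), c(300L, 240L))
  # straight vertical limb: row-wise intensity minima sit on the centreline
  limb <- tr$paths[[1]]$points[tr$paths[[1]]$points$arc_from_apex > 40, ]
  for (k in seq(1, nrow(limb), by = 20)) {
    row <- round(limb$y[k]) + 1
    expect_lt(abs(which.min(m$image[row, ]) - 1 - limb$x[k]), 1 + 1e-9)
  }
  # full width at half depth of the rendered profile equals the truth width
  row <- round(limb$y[10]) + 1
  prof <- m$image[row, ]
  bg <- max(prof); depth <- bg - min(prof)
  half <- min(prof) + depth / 2
  below <- which(prof < half)
  expect_equal(length(below), 12, tolerance = 1)

  expect_identical(render_mosaic(spec, tr)$image, m$image)
  # empty phantom: uniform background
  spec0 <- phantom_spec(n_capillaries = 0, noise_sd = 0,
                        texture_amplitude = 0, frame_shape = c(50, 60))
  m0 <- render_mosaic(spec0, phantom_truth(spec0))
  expect_true(all(m0$image == spec0$background))
  # frame too small for the geometry
  spec_bad <- phantom_spec(n_capillaries = 4, frame_shape = c(60, 100))
  expect_error(render_mosaic(spec_bad, phantom_truth(spec_bad)),
               class = "nailfold_geometry_error")
})

test_that("rendered video: advection matches velocity x frame interval", {
  # zero velocity, zero noise: all frames identical
  ph0 <- tiny_flow_phantom(velocity = 0, seed = 4, n_frames = 4,
                           noise_sd = 0)
  expect_identical(ph0$video$frames[[1]], ph0$video$frames[[4]])

  # doubling the frame rate halves the per-frame displacement: frame 3 at
  # 240 fps shows the cells exactly where frame 2 at 120 fps does
  sp1 <- phantom_spec(n_capillaries = 1, frame_shape = c(280, 200),
                      apex_y_um = 90, velocity_mm_s = 0.311, n_frames = 3,
                      frame_rate_hz = 120, noise_sd = 0, seed = 6)
  sp2 <- phantom_spec(n_capillaries = 1, frame_shape = c(280, 200),
                      apex_y_um = 90, velocity_mm_s = 0.311, n_frames = 3,
                      frame_rate_hz = 240, noise_sd = 0, seed = 6)
  v1 <- render_video(sp1, phantom_truth(sp1))
  v2 <- render_video(sp2, phantom_truth(sp2))
  expect_equal(v2$frames[[3]], v1$frames[[2]], tolerance = 1e-12)
  expect_identical(v1$frames[[1]], v2$frames[[1]])

  expect_error(render_video(phantom_spec(n_frames = 1),
                            phantom_truth(phantom_spec(n_frames = 1))),
               class = "nailfold_invalid_parameter")
})

test_that("overlapping tiles: layout, jitter bounds, determinism", {
  ph <- tile_phantom(seed = 2)
  step <- round(0.7 * 200)
  expect_equal(ph$true_offsets[, 1], c(0, step, 2 * step))
  expect_true(all(abs(ph$nominal_offsets - ph$true_offsets) <= 10))
  expect_identical(ph$nominal_offsets[1, ], ph$true_offsets[1, ])
  ph2 <- tile_phantom(seed = 2)
  expect_identical(ph$tiles, ph2$tiles)
  expect_identical(ph$nominal_offsets, ph2$nominal_offsets)

  spec <- ph$spec
  expect_error(render_overlapping_frames(spec, ph$truth, 1, 0.3),
               class = "nailfold_invalid_parameter")
  expect_error(render_overlapping_frames(spec, ph$truth, 3, 1.2),
               class = "nailfold_invalid_parameter")
  # zero jitter: nominal offsets equal true offsets
  ph0 <- render_overlapping_frames(spec, ph$truth, 3, 0.3, jitter_px = 0)
  expect_equal(ph0$nominal_offsets, ph0$true_offsets + 0)
})
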