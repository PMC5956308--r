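# Shared small phantom builders for the test suite.

# A single-capillary phantom video, small frames, auto-sized.
tiny_flow_phantom <- function(velocity = 0.311, seed = 1, n_frames = 12,
                              frame_rate = 120, noise_sd = 0.01) {
  spec <- phantom_spec(
    n_capillaries = 1, frame_shape = NULL, apex_y_um = 90,
    velocity_mm_s = velocity, n_frames = n_frames,
    frame_rate_hz = frame_rate, noise_sd = noise_sd, seed = seed
  )
  truth <- phantom_truth(spec)
  list(spec = spec, truth = truth, video = render_video(spec, truth))
}

# Ground-truth path reinterpreted in pixel units (1 um/px).
truth_path_px <- function(truth, i = 1) {
  p <- truth$paths[[i]]
  p$units <- "px"
  p$pixel_scale_um <- 1
  p
}

# Overlapping-tile phantom with known true offsets.
tile_phantom <- function(seed, n_tiles = 3, overlap = 0.3, noise_sd = 0.02) {
  spec <- phantom_spec(
    n_capillaries = 4, spacing_um = 80, frame_shape = c(280, 200),
    apex_y_um = 80, derangement_spread = 0.15, seed = seed,
    noise_sd = noise_sd
  )
  truth <- phantom_truth(spec,
                         frame_shape = virtual_frame_shape(spec, n_tiles,
                                                           overlap))
  c(list(spec = spec, truth = truth),
    render_overlapping_frames(spec, truth, n_tiles, overlap))
}

# A rendered still mosaic with its ridge map.
phantom_scene <- function(n = 4, seed = 1, width = 11.8, noise_sd = 0.01,
                          tortuosity = 0.2, spacing = 150, ...) {
  spec <- phantom_spec(n_capillaries = n, spacing_um = spacing,
                       width_um = width, frame_shape = NULL,
                       noise_sd = noise_sd, tortuosity = tortuosity,
                       seed = seed, ...)
  truth <- phantom_truth(spec)
  mosaic <- render_mosaic(spec, truth)
  list(spec = spec, truth = truth, mosaic = mosaic,
       ridge = ridge_map(mosaic$image, c(8, 12, 16), 1))
}

expect_nf_error <- function(expr, class) {
  expect_error(expr, class = class)
}
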