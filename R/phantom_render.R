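# Rendering phantoms to images: dark vessels on a bright background with a
# Gaussian cross-sectional profile whose full width at half the profile depth
# equals the ground-truth width. This width definition is shared with
# measure_widths(), so width ground truth is unambiguous.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

# Max-combine Gaussian stamps centred on the path points into `depth`.
# pts are 0-based pixel coordinates; sigma in px.
stamp_tube <- function(depth, px, py, sigma, amplitude) {
  nr <- nrow(depth); nc <- ncol(depth)
  sigma <- rep_len(sigma, length(px))
  rad <- ceiling(3.5 * sigma) + 1L
  for (k in seq_along(px)) {
    cx <- px[k]; cy <- py[k]; r <- rad[k]
    x0 <- max(0L, floor(cx) - r); x1 <- min(nc - 1L, ceiling(cx) + r)
    y0 <- max(0L, floor(cy) - r); y1 <- min(nr - 1L, ceiling(cy) + r)
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
    cand <- amplitude * exp(-d2 / (2 * sigma[k]^2))
    sub <- depth[ys + 1L, xs + 1L, drop = FALSE]
    depth[ys + 1L, xs + 1L] <- pmax(sub, cand)
  }
  depth
}

# Anisotropic Gaussian blob aligned with a tangent direction (for cells).
stamp_blob <- function(depth, cx, cy, theta, sigma_along, sigma_perp,
                       amplitude) {
  nr <- nrow(depth); nc <- ncol(depth)
  rad <- ceiling(3.5 * max(sigma_along, sigma_perp)) + 1L
  x0 <- max(0L, floor(cx) - rad); x1 <- min(nc - 1L, ceiling(cx) + rad)
  y0 <- max(0L, floor(cy) - rad); y1 <- min(nr - 1L, ceiling(cy) + rad)
  if (x1 < x0 || y1 < y0) return(depth)
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  dy <- matrix(ys - cy, length(ys), length(xs))
  a <- dx * cos(theta) + dy * sin(theta)
  b <- -dx * sin(theta) + dy * cos(theta)
  cand <- amplitude * exp(-a^2 / (2 * sigma_along^2) -
                          b^2 / (2 * sigma_perp^2))
  sub <- depth[ys + 1L, xs + 1L, drop = FALSE]
  depth[ys + 1L, xs + 1L] <- pmax(sub, cand)
  depth
}

# Smooth static scene texture emulating skin background structure.
scene_texture <- function(spec, dims) {
  if (spec$texture_amplitude <= 0) return(matrix(0, dims[1], dims[2]))
  with_seed(spec$seed + 5L, {
    g <- gaussian_kernel2(spec$texture_sigma_um / spec$pixel_scale_um)
    tex <- conv2(matrix(rnorm(prod(dims)), dims[1], dims[2]), g)
    tex <- tex - mean(tex)
    tex * (spec$texture_amplitude / sd(tex))
  })
}

phantom_dims <- function(spec, truth) {
  s <- spec$pixel_scale_um
  if (!is.null(spec$frame_shape)) return(spec$frame_shape)
  if (length(truth$paths) == 0) return(c(240L, 320L))
  xs <- unlist(lapply(truth$paths, function(p) p$points$x))
  ys <- unlist(lapply(truth$paths, function(p) p$points$y))
  marg <- max(45, 3.5 * max(truth$widths_um) * FWHM_TO_SIGMA + 10)
  c(ceiling((max(ys) + marg) / s), ceiling((max(xs) + marg) / s))
}

check_paths_fit <- function(truth, dims, s) {
  if (length(truth$paths) == 0) return(invisible(TRUE))
  for (p in truth$paths) {
    marg <- 2.5 * max(p$points$width_um) * FWHM_TO_SIGMA
    if (any(p$points$x - marg < 0) || any(p$points$y - marg < 0) ||
        any(p$points$x + marg > dims[2] * s) ||
        any(p$points$y + marg > dims[1] * s)) {
      nf_error("nailfold_geometry_error",
               "frame too small to contain the phantom capillary paths")
    }
  }
  invisible(TRUE)
}

render_vessel_depth <- function(truth, dims, s, amplitude) {
  depth <- matrix(0, dims[1], dims[2])
  for (p in truth$paths) {
    sig <- p$points$width_um * FWHM_TO_SIGMA / s
    depth <- stamp_tube(depth, p$points$x / s, p$points$y / s, sig, amplitude)
  }
  depth
}

#' Render a phantom still mosaic
#'
#' Dark tubes on a bright constant background: at each pixel the intensity is
#' `background - vessel_contrast * exp(-d^2 / (2 sigma^2))` where `d` is the
#' distance to the nearest centreline point and `sigma` is set so the full
#' width at half the profile depth equals the ground-truth width. Additive
#' Gaussian noise of SD `spec$noise_sd` is applied (deterministically from
#' `spec$seed`). Intensity minima lie on the centrelines.
#'
#' @param spec a [phantom_spec()].
#' @param truth the matching [phantom_truth()].
#' @param noise_sd override for `spec$noise_sd`.
#' @return a `nailfold_mosaic`: `image` (matrix in \[0, 1\], rows = y),
#'   `pixel_scale_um`, `frame_offsets = NULL`.
#' @export
render_mosaic <- function(spec, truth, noise_sd = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(truth, "phantom_truth"))
  s <- spec$pixel_scale_um
  dims <- phantom_dims(spec, truth)
  check_paths_fit(truth, dims, s)
  depth <- render_vessel_depth(truth, dims, s, spec$vessel_contrast)
  nsd <- noise_sd %||% spec$noise_sd
  img <- spec$background + scene_texture(spec, dims) - depth
  if (nsd > 0) {
    img <- img + with_seed(spec$seed + 1L,
                           matrix(rnorm(length(img), 0, nsd), nrow(img)))
  }
  structure(list(
    image = clamp01(img),
    pixel_scale_um = s,
    frame_offsets = NULL,
    source_frame_count = 1L
  ), class = "nailfold_mosaic")
}

# Poisson-spaced cell arc positions along a path of total length L.
seed_cells <- function(L, mean_gap) {
  pos <- cumsum(rexp(ceiling(2 * L / mean_gap) + 5, 1 / mean_gap))
  pos[pos < L]
}

#' Render a phantom video sequence
#'
#' Static vessel walls (contrast `spec$wall_contrast`) plus dark elliptical
#' cell blobs advected along each centreline at the capillary's ground-truth
#' speed, with Poisson-spaced plasma gaps. The per-frame along-path
#' displacement is `velocity_mm_s * 1000 / frame_rate_hz` micrometres; cells
#' leaving the venous end re-enter at the arterial end. Cell contrast exceeds
#' wall contrast so the temporal signal dominates along the lumen.
#'
#' @inheritParams render_mosaic
#' @return a [video_sequence()] of `spec$n_frames` frames with zero nominal
#'   offsets (static camera).
#' @export
render_video <- function(spec, truth) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(truth, "phantom_truth"))
  if (spec$n_frames < 2) {
    nf_error("nailfold_invalid_parameter", "n_frames must be >= 2")
  }
  s <- spec$pixel_scale_um
  dims <- phantom_dims(spec, truth)
  check_paths_fit(truth, dims, s)
  walls <- render_vessel_depth(truth, dims, s, spec$wall_contrast)
  tex <- scene_texture(spec, dims)
  n <- length(truth$paths)
  geo <- lapply(truth$paths, function(p) {
    arc <- p$points$arc_from_apex - min(p$points$arc_from_apex)
    list(arc = arc, L = max(arc), x = p$points$x, y = p$points$y,
         ori = p$points$orientation)
  })
  cells0 <- with_seed(spec$seed + 2L, lapply(seq_len(max(n, 1)), function(i) {
    if (n == 0) numeric(0) else seed_cells(geo[[i]]$L, spec$cell_spacing_um)
  }))
  dpf <- truth$velocities_mm_s * 1000 / spec$frame_rate_hz  # um per frame
  noise <- if (spec$noise_sd > 0) {
    with_seed(spec$seed + 3L, lapply(seq_len(spec$n_frames), function(t) {
      matrix(rnorm(prod(dims), 0, spec$noise_sd), dims[1])
    }))
  }
  frames <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    depth <- matrix(0, dims[1], dims[2])
    for (i in seq_len(n)) {
      g <- geo[[i]]
      pos <- (cells0[[i]] + (t - 1) * dpf[i]) %% g$L
      cx <- approx(g$arc, g$x, pos, rule = 2)$y / s
      cy <- approx(g$arc, g$y, pos, rule = 2)$y / s
      th <- g$ori[pmax(1, round(approx(g$arc, seq_along(g$arc), pos,
                                       rule = 2)$y))]
      sp <- truth$widths_um[i] * FWHM_TO_SIGMA / s * 0.8
      for (k in seq_along(pos)) {
        depth <- stamp_blob(depth, cx[k], cy[k], th[k],
                            1.4 * sp, sp, spec$cell_contrast)
      }
    }
    img <- spec$background + tex - pmax(walls, depth)
    if (!is.null(noise)) img <- img + noise[[t]]
    frames[[t]] <- clamp01(img)
  }
  video_sequence(frames, spec$frame_rate_hz, s,
                 nominal_offsets = matrix(0, spec$n_frames, 2))
}

#' Virtual canvas shape for overlapping-tile phantoms
#'
#' @param spec a [phantom_spec()] whose `frame_shape` is the tile shape.
#' @param n_tiles,overlap_frac tiling layout.
#' @return `c(height, width)` of the wide virtual nailfold in px.
#' @export
virtual_frame_shape <- function(spec, n_tiles, overlap_frac) {
  tw <- spec$frame_shape[2]
  step <- round((1 - overlap_frac) * tw)
  c(spec$frame_shape[1], tw + (n_tiles - 1) * step)
}

#' Render overlapping sub-frames from a wide virtual nailfold
#'
#' Emulates the motorised-stage capture: the virtual nailfold is rendered
#' noise-free, cropped into `n_tiles` tiles whose adjacent pairs share
#' `overlap_frac` of their width, and each tile receives independent noise.
#' Nominal offsets are the true translations plus bounded uniform jitter,
#' emulating imperfect motor tracking. Generate `truth` with
#' `phantom_truth(spec, frame_shape = virtual_frame_shape(...))` so the
#' capillaries span the virtual canvas.
#'
#' @inheritParams render_mosaic
#' @param n_tiles number of tiles (>= 2).
#' @param overlap_frac fraction of tile width shared by adjacent tiles,
#'   in (0, 1).
#' @param jitter_px max abs jitter of the nominal offsets (<= 10).
#' @return list with `tiles` (list of matrices), `true_offsets` and
#'   `nominal_offsets` (n_tiles x 2, px, relative to the first tile) and
#'   `virtual_image`.
#' @export
render_overlapping_frames <- function(spec, truth, n_tiles, overlap_frac,
                                      jitter_px = 8) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(truth, "phantom_truth"))
  if (n_tiles < 2) {
    nf_error("nailfold_invalid_parameter", "n_tiles must be >= 2")
  }
  if (overlap_frac <= 0 || overlap_frac >= 1) {
    nf_error("nailfold_invalid_parameter", "overlap_frac must be in (0, 1)")
  }
  if (jitter_px > 10) {
    nf_error("nailfold_invalid_parameter", "jitter_px must be <= 10")
  }
  th <- spec$frame_shape[1]; tw <- spec$frame_shape[2]
  step <- round((1 - overlap_frac) * tw)
  dims <- virtual_frame_shape(spec, n_tiles, overlap_frac)
  s <- spec$pixel_scale_um
  check_paths_fit(truth, dims, s)
  virtual <- render_vessel_depth(truth, dims, s, spec$vessel_contrast)
  virtual <- spec$background + scene_texture(spec, dims) - virtual
  true_off <- cbind(dx = (seq_len(n_tiles) - 1) * step, dy = 0)
  with_seed(spec$seed + 4L, {
    jit <- matrix(runif(2 * n_tiles, -jitter_px, jitter_px), ncol = 2)
    jit[1, ] <- 0
    tiles <- lapply(seq_len(n_tiles), function(i) {
      tile <- virtual[seq_len(th), true_off[i, 1] + seq_len(tw)]
      if (spec$noise_sd > 0) {
        tile <- tile + matrix(rnorm(length(tile), 0, spec$noise_sd), th)
      }
      clamp01(tile)
    })
    list(tiles = tiles, true_offsets = true_off,
         nominal_offsets = true_off + jit, virtual_image = clamp01(virtual))
  })
}
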