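# Software phantom: parametric ground-truth geometry for hairpin-shaped
# distal-row capillaries. All geometry is stored in micrometres; conversion
# to pixels happens only at render time.

#' Phantom specification
#'
#' Parameters of a synthetic nailfold: how many hairpin capillaries to place,
#' their spacing, widths, limb length, tortuosity (SD of the smooth angular
#' wobble added to the limb tangent, radians), derangement spread (SD of the
#' per-capillary principal orientation about vertical, radians), ground-truth
#' cell speed, and the imaging geometry (frame rate, pixel scale, frame
#' shape, noise level). Defaults mimic a healthy-control nailfold imaged at
#' 120 frames/s with 1 um pixels on a 640 x 480 sensor: ~150 um apex
#' spacing, 11.8 um wide capillaries flowing at 0.311 mm/s.
#'
#' @param n_capillaries number of hairpins.
#' @param spacing_um mean inter-apex distance (um).
#' @param width_um capillary width(s), recycled across capillaries (um).
#' @param limb_length_um limb arc length from the apex turn (um).
#' @param tortuosity SD of the limb orientation wobble (radians, >= 0).
#' @param derangement_spread SD of principal orientations about vertical
#'   (radians, >= 0).
#' @param velocity_mm_s ground-truth cell speed(s), recycled (mm/s, >= 0).
#' @param frame_rate_hz video frame rate.
#' @param pixel_scale_um micrometres per pixel.
#' @param frame_shape `c(height, width)` in pixels, or `NULL` to auto-size
#'   frames around the generated geometry at render time.
#' @param noise_sd additive Gaussian intensity noise SD (image intensities
#'   lie in \[0, 1\]).
#' @param n_frames frames per rendered video sequence.
#' @param seed RNG seed; every generator output is a pure function of
#'   (spec, seed).
#' @param background,vessel_contrast,wall_contrast,cell_contrast photometric
#'   model: background level, centreline depth of the vessel in the still
#'   mosaic, wall depth in video frames, and cell-blob depth.
#' @param cell_spacing_um mean arc-length gap between cells (um).
#' @param texture_amplitude,texture_sigma_um SD (intensity) and correlation
#'   length (um) of the smooth static scene texture that emulates skin
#'   background structure (0 disables it).
#' @param apex_radius_factor apex turn radius as a multiple of local width.
#' @param apex_y_um depth of the apex row below the frame top (um).
#' @param position_jitter_um `c(x, y)` uniform jitter of apex positions (um).
#' @return a `phantom_spec` list.
#' @seealso [phantom_truth()], [render_mosaic()], [render_video()]
#' @export
phantom_spec <- function(n_capillaries = 4, spacing_um = 150, width_um = 11.8,
                         limb_length_um = 100, tortuosity = 0.2,
                         derangement_spread = 0.25, velocity_mm_s = 0.311,
                         frame_rate_hz = 120, pixel_scale_um = 1,
                         frame_shape = c(480L, 640L), noise_sd = 0.01,
                         n_frames = 30, seed = 1, background = 0.85,
                         vessel_contrast = 0.45, wall_contrast = 0.15,
                         cell_contrast = 0.5, cell_spacing_um = 15,
                         texture_amplitude = 0.04, texture_sigma_um = 12,
                         apex_radius_factor = 1.5, apex_y_um = 150,
                         position_jitter_um = c(15, 10)) {
  check_pos(n_capillaries, "n_capillaries", allow_zero = TRUE)
  check_pos(spacing_um, "spacing_um")
  check_pos(width_um, "width_um")
  check_pos(limb_length_um, "limb_length_um")
  check_pos(tortuosity, "tortuosity", allow_zero = TRUE)
  check_pos(derangement_spread, "derangement_spread", allow_zero = TRUE)
  check_pos(velocity_mm_s, "velocity_mm_s", allow_zero = TRUE)
  check_pos(frame_rate_hz, "frame_rate_hz")
  check_pos(pixel_scale_um, "pixel_scale_um")
  check_pos(noise_sd, "noise_sd", allow_zero = TRUE)
  check_pos(texture_amplitude, "texture_amplitude", allow_zero = TRUE)
  check_pos(texture_sigma_um, "texture_sigma_um")
  check_pos(n_frames, "n_frames")
  if (!is.null(frame_shape)) {
    check_pos(frame_shape, "frame_shape")
    frame_shape <- as.integer(round(frame_shape))
  }
  structure(as.list(environment()), class = "phantom_spec")
}

# Smooth, zero-anchored angular noise along a limb: white noise integrated
# and band-limited by a moving average, rescaled to the target SD.
smooth_angular_noise <- function(n, sd_target, window = 15) {
  if (sd_target <= 0 || n < 2) return(numeric(n))
  w <- cumsum(rnorm(n))
  k <- min(window, n)
  sm <- as.numeric(stats::filter(c(rep(w[1], k), w, rep(w[n], k)),
                                 rep(1 / k, k), sides = 2))
  sm <- sm[(k + 1):(k + n)]
  sm <- sm - sm[1]
  s <- sd(sm)
  if (!is.finite(s) || s == 0) return(numeric(n))
  sm * (sd_target / s)
}

#' Generate one ground-truth hairpin capillary path
#'
#' Two limbs of arc length `limb_length_um`, joined at the apex by a
#' semicircular turn of radius `apex_radius_um`, sampled at `step_um`
#' arc-length steps. Each point carries its position (um), local tangent
#' orientation (radians mod pi) and width (um). With `tortuosity = 0` the
#' limbs are straight and parallel to `principal_orientation`; otherwise a
#' smooth band-limited angular wobble with SD `tortuosity` is added to the
#' limb tangents (the turn is kept clean so the apex stays well defined).
#' Uses the current RNG state; call inside a seeded context for
#' reproducibility.
#'
#' @param apex_xy apex coordinates `c(x, y)` in um (y grows downward).
#' @param principal_orientation limb axis, radians mod pi.
#' @param width_um capillary width (um).
#' @param limb_length_um limb arc length (um).
#' @param tortuosity SD of the tangent wobble (radians, >= 0).
#' @param apex_radius_um turn radius; default 1.5 x width.
#' @param step_um arc-length sampling step (um).
#' @return a `capillary_path` with `units = "um"`: `points` (data.frame
#'   `x`, `y`, `orientation`, `width_um`, `arc_from_apex`), `apex_xy`,
#'   `apex_index`, `limb_arc_lengths`.
#' @export
make_capillary_path <- function(apex_xy, principal_orientation, width_um,
                                limb_length_um = 100, tortuosity = 0,
                                apex_radius_um = NULL, step_um = 1) {
  check_pos(width_um, "width_um")
  check_pos(limb_length_um, "limb_length_um")
  check_pos(step_um, "step_um")
  check_pos(tortuosity, "tortuosity", allow_zero = TRUE)
  r <- apex_radius_um %||% (1.5 * width_um)
  check_pos(r, "apex_radius_um")

  phi <- principal_orientation %% pi
  u <- c(cos(phi), sin(phi))
  if (u[2] < 0) u <- -u            # limbs run down the image (y grows down)
  v <- c(-u[2], u[1])
  ctr <- apex_xy + r * u

  # Apex turn: p(psi) = ctr - r (u cos psi - v sin psi), psi in [-pi/2, pi/2];
  # psi = 0 is the apex itself. Odd number of samples keeps the apex on-grid.
  npsi <- ceiling(pi * r / step_um) + 1
  if (npsi %% 2 == 0) npsi <- npsi + 1
  psi <- seq(-pi / 2, pi / 2, length.out = npsi)
  tx <- ctr[1] - r * (u[1] * cos(psi) - v[1] * sin(psi))
  ty <- ctr[2] - r * (u[2] * cos(psi) - v[2] * sin(psi))
  tor <- atan2(u[2] * sin(psi) + v[2] * cos(psi),
               u[1] * sin(psi) + v[1] * cos(psi)) %% pi
  turn_arc <- r * (psi + pi / 2)   # arc distance from the arterial turn end

  limb <- function(origin) {
    m <- ceiling(limb_length_um / step_um)
    th <- smooth_angular_noise(m, tortuosity)
    h <- atan2(u[2], u[1]) + th
    list(x = origin[1] + cumsum(step_um * cos(h)),
         y = origin[2] + cumsum(step_um * sin(h)),
         orientation = h %% pi,
         arc = step_um * seq_len(m))
  }
  la <- limb(c(tx[1], ty[1]))       # arterial limb, away from the turn
  lb <- limb(c(tx[npsi], ty[npsi])) # venous limb

  apex_i <- (npsi + 1) / 2
  x <- c(rev(la$x), tx, lb$x)
  y <- c(rev(la$y), ty, lb$y)
  ori <- c(rev(la$orientation), tor, lb$orientation)
  arc_apex <- turn_arc[apex_i]
  arc <- c(-(rev(la$arc) + arc_apex), turn_arc - arc_apex,
           lb$arc + (turn_arc[npsi] - arc_apex))
  pts <- data.frame(x = x, y = y, orientation = ori,
                    width_um = width_um, arc_from_apex = arc)
  structure(list(
    points = pts,
    apex_xy = c(tx[apex_i], ty[apex_i]),
    apex_index = length(la$x) + apex_i,
    limb_arc_lengths = c(arterial = limb_length_um, venous = limb_length_um),
    units = "um",
    pixel_scale_um = 1
  ), class = "capillary_path")
}

#' Generate phantom ground truth from a specification
#'
#' Places `n_capillaries` apices left to right at jittered `spacing_um`
#' intervals, draws principal orientations from a wrapped normal about
#' vertical with SD `derangement_spread`, and builds each hairpin with
#' [make_capillary_path()]. Deterministic given `(spec, spec$seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param frame_shape optional `c(height, width)` override in px used to
#'   centre the apex span (e.g. the virtual canvas of
#'   [render_overlapping_frames()]).
#' @return a `phantom_truth` list: `paths`, `apices` (n x 2 matrix, um),
#'   `principal_orientations` (realised axial means, mod pi),
#'   `velocities_mm_s`, `widths_um`, `frame_offsets` (n_frames x 2, px),
#'   `density_truth` (apices per mm over the leftmost-to-rightmost span;
#'   NA when n < 2).
#' @export
phantom_truth <- function(spec, frame_shape = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_capillaries
  shape <- frame_shape %||% spec$frame_shape
  with_seed(spec$seed, {
    widths <- rep_len(spec$width_um, max(n, 1))
    vels <- rep_len(spec$velocity_mm_s, max(n, 1))
    if (n > 0) {
      span <- (n - 1) * spec$spacing_um
      x0 <- if (is.null(shape)) {
        spec$spacing_um / 2 + 40
      } else {
        (shape[2] * spec$pixel_scale_um - span) / 2
      }
      ax <- x0 + (seq_len(n) - 1) * spec$spacing_um +
        runif(n, -1, 1) * spec$position_jitter_um[1]
      ay <- spec$apex_y_um + runif(n, -1, 1) * spec$position_jitter_um[2]
      oris <- (pi / 2 + rnorm(n, 0, spec$derangement_spread)) %% pi
      paths <- lapply(seq_len(n), function(i) {
        make_capillary_path(c(ax[i], ay[i]), oris[i], widths[i],
                            spec$limb_length_um, spec$tortuosity)
      })
      apices <- cbind(x = ax, y = ay)
      if (is.null(shape)) {
        # auto-sized canvas: translate so the widest path clears the left edge
        pad <- 2.5 * max(widths) * FWHM_TO_SIGMA + 25
        dx <- pad - min(vapply(paths, function(p) min(p$points$x), 0))
        if (dx > 0) {
          paths <- lapply(paths, function(p) {
            p$points$x <- p$points$x + dx
            p$apex_xy[1] <- p$apex_xy[1] + dx
            p
          })
          apices[, 1] <- apices[, 1] + dx
        }
      }
      realised_oris <- vapply(paths, function(p) {
        axial_mean_orientation(p$points$orientation)
      }, 0)
    } else {
      paths <- list(); apices <- cbind(x = numeric(0), y = numeric(0))
      realised_oris <- numeric(0); widths <- numeric(0); vels <- numeric(0)
    }
    density <- if (n >= 2) n / (diff(range(apices[, 1])) / 1000) else NA_real_
    structure(list(
      paths = paths,
      apices = apices,
      principal_orientations = realised_oris,
      velocities_mm_s = vels,
      widths_um = widths,
      frame_offsets = matrix(0, nrow = spec$n_frames, ncol = 2),
      density_truth = density
    ), class = "phantom_truth")
  })
}
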