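# Optical-flow red-blood-cell velocimetry: dense gradient-based (Lucas-
# Kanade style) flow with local window aggregation, a two-level pyramid and
# iterative warping, then projection of the flow onto the capillary path.

warp_image <- function(img, vx, vy) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  gy <- matrix(0:(nr - 1), nr, nc)
  w <- interp_bilinear(img, gx + vx, gy + vy)
  bad <- !is.finite(w)
  w[bad] <- img[bad]
  list(image = matrix(w, nr, nc), ok = matrix(!bad, nr, nc))
}

lk_refine <- function(a, b, vx, vy, window, n_iter, min_eig) {
  r <- (window - 1) %/% 2
  ok_all <- matrix(TRUE, nrow(a), ncol(a))
  for (it in seq_len(n_iter)) {
    wb <- warp_image(b, vx, vy)
    ok_all <- ok_all & wb$ok
    It <- wb$image - a
    Ix <- 0.5 * (shift_dx(a) + shift_dx(wb$image))
    Iy <- 0.5 * (shift_dy(a) + shift_dy(wb$image))
    Sxx <- box_sum(Ix * Ix, r); Sxy <- box_sum(Ix * Iy, r)
    Syy <- box_sum(Iy * Iy, r)
    Sxt <- box_sum(Ix * It, r); Syt <- box_sum(Iy * It, r)
    det <- Sxx * Syy - Sxy^2
    lmin <- 0.5 * ((Sxx + Syy) - sqrt((Sxx - Syy)^2 + 4 * Sxy^2))
    good <- is.finite(det) & abs(det) > 1e-12 & lmin / window^2 > min_eig
    dvx <- ifelse(good, -(Syy * Sxt - Sxy * Syt) / det, 0)
    dvy <- ifelse(good, -(Sxx * Syt - Sxy * Sxt) / det, 0)
    dvx <- pmax(-2, pmin(2, dvx))
    dvy <- pmax(-2, pmin(2, dvy))
    vx <- vx + dvx
    vy <- vy + dvy
  }
  list(vx = vx, vy = vy, valid = good & ok_all, lmin = lmin)
}

#' Dense optical flow between two frames
#'
#' Gradient-based flow minimising the brightness-constancy residual over a
#' square aggregation window, solved per pixel from the local structure
#' tensor, with iterative warping and a two-level coarse-to-fine pyramid to
#' handle multi-pixel displacements. Pixels whose structure tensor is
#' degenerate (aperture problem: the smallest eigenvalue per window pixel
#' falls below `min_eig`) are marked invalid.
#'
#' @param frame_a,frame_b 2D grayscale matrices of one shape.
#' @param mask optional logical matrix; pixels outside it are invalid.
#' @param window aggregation window side (px, odd).
#' @param n_iter warp iterations per pyramid level.
#' @param pyramid_levels 1 (none) or 2.
#' @param smooth_sigma Gaussian pre-smoothing SD (px).
#' @param min_eig structure-tensor conditioning threshold (per window pixel).
#' @return a `flow_field`: `vx`, `vy` (px/frame, displacement of frame_a
#'   content between the frames) and logical `valid`.
#' @export
estimate_flow <- function(frame_a, frame_b, mask = NULL, window = 15,
                          n_iter = 3, pyramid_levels = 2, smooth_sigma = 1.5,
                          min_eig = 2e-5) {
  if (!identical(dim(frame_a), dim(frame_b))) {
    nf_error("nailfold_invalid_input", "frames must share one shape")
  }
  g <- gaussian_kernel2(smooth_sigma)
  a <- conv2(frame_a, g)
  b <- conv2(frame_b, g)
  vx <- vy <- matrix(0, nrow(a), ncol(a))
  if (pyramid_levels >= 2 && min(dim(a)) >= 2 * window) {
    a2 <- downsample2(a); b2 <- downsample2(b)
    f2 <- lk_refine(a2, b2, matrix(0, nrow(a2), ncol(a2)),
                    matrix(0, nrow(a2), ncol(a2)),
                    window = max(7, (window %/% 2) %/% 2 * 2 + 1),
                    n_iter = n_iter, min_eig = min_eig)
    vx <- 2 * upsample_to(f2$vx, nrow(a), ncol(a))
    vy <- 2 * upsample_to(f2$vy, nrow(a), ncol(a))
  }
  fl <- lk_refine(a, b, vx, vy, window, n_iter, min_eig)
  valid <- fl$valid
  if (!is.null(mask)) valid <- valid & mask
  structure(list(vx = fl$vx, vy = fl$vy, valid = valid),
            class = "flow_field")
}

#' Per-frame apex visibility
#'
#' A capillary contributes a frame to the flow estimate only when its apex
#' lies inside that frame (mapped through the stage offset) with at least
#' `margin_px` of margin.
#'
#' @param video a [video_sequence()].
#' @param apex_xy apex position in mosaic coordinates (0-based px).
#' @param frame_offsets per-frame `(dx, dy)` px; defaults to the video's
#'   nominal offsets, else zeros.
#' @param margin_px required margin.
#' @return logical vector, one flag per frame.
#' @export
apex_visibility <- function(video, apex_xy, frame_offsets = NULL,
                            margin_px = 20) {
  stopifnot(inherits(video, "video_sequence"))
  offs <- frame_offsets %||% video$nominal_offsets %||%
    matrix(0, length(video$frames), 2)
  dims <- dim(video$frames[[1]])
  fx <- apex_xy[1] - offs[, 1]
  fy <- apex_xy[2] - offs[, 2]
  fx >= margin_px & fx <= dims[2] - 1 - margin_px &
    fy >= margin_px & fy <= dims[1] - 1 - margin_px
}

#' Mean cell velocity along one capillary path
#'
#' For every consecutive pair of frames in which the apex is visible, the
#' optical flow is estimated on a crop around the path, sampled at the path
#' points, and projected onto the local path tangent. The per-pair speed is
#' the mean absolute projection over path points that are flow-valid and
#' *motion-active* (local temporal-difference energy above a robust
#' threshold, so static wall texture between cells does not dilute the
#' estimate); a pair with no active point contributes speed 0. Speeds are
#' converted px/frame -> mm/s via
#' `pixel_scale_um x frame_rate_hz / 1000`, and the capillary speed is the
#' mean over pairs. Speed (not signed velocity) is reported: the
#' arterial-vs-venous sign is not defined for an axial path.
#'
#' @param video a [video_sequence()].
#' @param path a `capillary_path` in px units (mosaic coordinates).
#' @param apex_visible optional per-frame flags; computed by
#'   [apex_visibility()] when absent.
#' @param window flow aggregation window (px).
#' @param margin_px crop margin around the path (px).
#' @param trim fraction trimmed from each tail of the per-pair speeds before
#'   averaging (default 0: plain mean, no outlier rejection).
#' @param capillary_id identifier copied into the result.
#' @return a `capillary_flow`: `capillary_id`, `mean_velocity_mm_s`,
#'   `per_frame_speeds` (mm/s, one per frame pair), `n_frames_used`.
#'   Raises `nailfold_flow_error` with fewer than 2 visible frames.
#' @export
capillary_velocity <- function(video, path, apex_visible = NULL,
                               window = 15, margin_px = 25, trim = 0,
                               capillary_id = 1L) {
  stopifnot(inherits(video, "video_sequence"))
  vis <- apex_visible %||% apex_visibility(video, path$apex_xy)
  idx <- which(vis)
  if (length(idx) < 2) {
    nf_error("nailfold_flow_error",
             sprintf("capillary %s: fewer than 2 frames with visible apex",
                     capillary_id))
  }
  offs <- video$nominal_offsets %||% matrix(0, length(video$frames), 2)
  dims <- dim(video$frames[[1]])
  pts <- path$points
  s <- video$pixel_scale_um
  pairs <- idx[which(diff(idx) == 1)]
  if (length(pairs) < 1) {
    nf_error("nailfold_flow_error",
             sprintf("capillary %s: no consecutive visible frame pair",
                     capillary_id))
  }
  speeds <- vapply(pairs, function(i) {
    px <- pts$x - offs[i, 1]
    py <- pts$y - offs[i, 2]
    x0 <- max(0, floor(min(px)) - margin_px)
    x1 <- min(dims[2] - 1, ceiling(max(px)) + margin_px)
    y0 <- max(0, floor(min(py)) - margin_px)
    y1 <- min(dims[1] - 1, ceiling(max(py)) + margin_px)
    a <- video$frames[[i]][(y0:y1) + 1, (x0:x1) + 1]
    b <- video$frames[[i + 1]][(y0:y1) + 1, (x0:x1) + 1]
    fl <- estimate_flow(a, b, window = window)
    r <- (window - 1) %/% 2
    act <- box_sum(abs(b - a), r) / box_count(nrow(a), ncol(a), r)
    # noise floor: the bulk of the crop is static, so the median tracks the
    # sensor noise; motion must clear it by both a ratio and a robust spread
    thr <- max(1.5 * median(act), median(act) + 6 * stats::mad(act), 1e-9)
    cx <- px - x0; cy <- py - y0
    fvx <- interp_bilinear(fl$vx, cx, cy)
    fvy <- interp_bilinear(fl$vy, cx, cy)
    fva <- interp_bilinear(act, cx, cy)
    vok <- interp_bilinear(fl$valid * 1, cx, cy)
    use <- is.finite(fvx) & is.finite(fva) & fva > thr &
      is.finite(vok) & vok > 0.99
    if (!any(use)) return(0)
    proj <- fvx * cos(pts$orientation) + fvy * sin(pts$orientation)
    mean(abs(proj[use]))
  }, 0)
  speeds_mm_s <- speeds * s * video$frame_rate_hz / 1000
  structure(list(
    capillary_id = capillary_id,
    mean_velocity_mm_s = mean(speeds_mm_s, trim = trim),
    per_frame_speeds = speeds_mm_s,
    n_frames_used = length(idx)
  ), class = "capillary_flow")
}
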