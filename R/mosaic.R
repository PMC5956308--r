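# Translation-only frame registration and mosaic compositing. The motorised
# stage moves in-plane, so a pure-translation model suffices; overlapping
# pixels are combined by per-pixel mean, which also denoises the composite.

#' Video sequence container
#'
#' @param frames list of 2D grayscale matrices (rows = y), all one shape.
#' @param frame_rate_hz frames per second.
#' @param pixel_scale_um micrometres per pixel.
#' @param nominal_offsets optional n x 2 matrix of per-frame `(dx, dy)` px
#'   from stage tracking, relative to the first frame.
#' @return a `video_sequence` list.
#' @export
video_sequence <- function(frames, frame_rate_hz, pixel_scale_um,
                           nominal_offsets = NULL) {
  check_pos(frame_rate_hz, "frame_rate_hz")
  check_pos(pixel_scale_um, "pixel_scale_um")
  if (length(frames) < 1) {
    nf_error("nailfold_invalid_parameter", "at least one frame is required")
  }
  dims <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), dims), TRUE))) {
    nf_error("nailfold_invalid_parameter", "all frames must share one shape")
  }
  if (!is.null(nominal_offsets)) {
    nominal_offsets <- matrix(as.numeric(nominal_offsets), ncol = 2)
    stopifnot(nrow(nominal_offsets) == length(frames))
  }
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 pixel_scale_um = pixel_scale_um,
                 nominal_offsets = nominal_offsets),
            class = "video_sequence")
}

overlap_cor <- function(fixed, moving, dx, dy) {
  nf <- dim(fixed); nm <- dim(moving)
  x0 <- max(0, dx); x1 <- min(nf[2] - 1, dx + nm[2] - 1)
  y0 <- max(0, dy); y1 <- min(nf[1] - 1, dy + nm[1] - 1)
  if (x1 < x0 || y1 < y0) return(list(score = NA_real_, n = 0))
  a <- fixed[(y0:y1) + 1, (x0:x1) + 1]
  b <- moving[(y0:y1) - dy + 1, (x0:x1) - dx + 1]
  s <- suppressWarnings(cor(as.vector(a), as.vector(b)))
  list(score = if (is.finite(s)) s else NA_real_, n = length(a))
}

parabolic_peak <- function(sm1, s0, sp1) {
  den <- sm1 - 2 * s0 + sp1
  if (!is.finite(den) || den >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (sm1 - sp1) / den))
}

#' Register one frame pair by translation
#'
#' Normalised cross-correlation over an integer search window of
#' `search_radius` px around the nominal `initial_offset`, followed by
#' parabolic sub-pixel refinement of the correlation peak. Offsets place the
#' moving frame's origin in the fixed frame's 0-based pixel coordinates.
#'
#' @param fixed,moving 2D grayscale matrices.
#' @param initial_offset nominal `(dx, dy)` in px.
#' @param search_radius half-width of the search window (px).
#' @return list with `offset` (refined, sub-pixel) and `score` in \[-1, 1\].
#'   Raises a `nailfold_registration_error` (carrying the nominal offset in
#'   `$fallback_offset`) when the overlap at the initial offset is below 10%
#'   of the moving frame area.
#' @export
register_pair <- function(fixed, moving, initial_offset = c(0, 0),
                          search_radius = 20) {
  ix <- round(initial_offset[1]); iy <- round(initial_offset[2])
  ov0 <- overlap_cor(fixed, moving, ix, iy)
  if (ov0$n < 0.1 * length(moving)) {
    nf_error("nailfold_registration_error",
             "insufficient overlap at the initial offset",
             fallback_offset = as.numeric(initial_offset))
  }
  dxs <- (ix - search_radius):(ix + search_radius)
  dys <- (iy - search_radius):(iy + search_radius)
  scores <- matrix(NA_real_, length(dys), length(dxs))
  for (j in seq_along(dxs)) {
    for (i in seq_along(dys)) {
      ov <- overlap_cor(fixed, moving, dxs[j], dys[i])
      if (ov$n >= 0.05 * length(moving)) scores[i, j] <- ov$score
    }
  }
  if (!any(is.finite(scores))) {
    nf_error("nailfold_registration_error",
             "no valid correlation in the search window",
             fallback_offset = as.numeric(initial_offset))
  }
  best <- which(scores == max(scores, na.rm = TRUE), arr.ind = TRUE)[1, ]
  bi <- best[1]; bj <- best[2]
  ddx <- ddy <- 0
  if (bj > 1 && bj < ncol(scores) &&
      all(is.finite(scores[bi, (bj - 1):(bj + 1)]))) {
    ddx <- parabolic_peak(scores[bi, bj - 1], scores[bi, bj],
                          scores[bi, bj + 1])
  }
  if (bi > 1 && bi < nrow(scores) &&
      all(is.finite(scores[(bi - 1):(bi + 1), bj]))) {
    ddy <- parabolic_peak(scores[bi - 1, bj], scores[bi, bj],
                          scores[bi + 1, bj])
  }
  list(offset = c(dxs[bj] + ddx, dys[bi] + ddy), score = scores[bi, bj])
}

#' Compose a video sequence into a mosaic
#'
#' Chains pairwise registrations (each seeded by the nominal stage offsets)
#' to place every frame relative to the first, then composites by per-pixel
#' mean. A pair whose registration fails or scores below `min_score` falls
#' back to its nominal offset; the mosaic is then flagged.
#'
#' @param video a [video_sequence()].
#' @param search_radius search half-width passed to [register_pair()].
#' @param min_score minimum acceptable pairwise correlation.
#' @return a `nailfold_mosaic`: `image`, `frame_offsets` (n x 2, sub-pixel,
#'   relative to frame 1 at (0, 0)), `pixel_scale_um`, `source_frame_count`,
#'   `quality_ok`, `registration_warnings`.
#' @export
compose_mosaic <- function(video, search_radius = 20, min_score = 0.3) {
  stopifnot(inherits(video, "video_sequence"))
  frames <- video$frames
  n <- length(frames)
  nom <- video$nominal_offsets %||% matrix(0, n, 2)
  offs <- matrix(0, n, 2)
  warnings <- character(0)
  for (i in seq_len(n)[-1]) {
    init <- nom[i, ] - nom[i - 1, ]
    reg <- tryCatch(
      register_pair(frames[[i - 1]], frames[[i]], init, search_radius),
      nailfold_registration_error = function(e) NULL
    )
    if (is.null(reg) || !is.finite(reg$score) || reg$score < min_score) {
      warnings <- c(warnings,
                    sprintf("frame %d: registration fell back to nominal offset", i))
      delta <- init
    } else {
      delta <- reg$offset
    }
    offs[i, ] <- offs[i - 1, ] + delta
  }
  ro <- round(offs)
  dims <- dim(frames[[1]])
  x0 <- min(ro[, 1]); y0 <- min(ro[, 2])
  W <- max(ro[, 1]) - x0 + dims[2]
  H <- max(ro[, 2]) - y0 + dims[1]
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (i in seq_len(n)) {
    ry <- ro[i, 2] - y0 + seq_len(dims[1])
    rx <- ro[i, 1] - x0 + seq_len(dims[2])
    acc[ry, rx] <- acc[ry, rx] + frames[[i]]
    cnt[ry, rx] <- cnt[ry, rx] + 1
  }
  img <- acc / pmax(cnt, 1)
  structure(list(
    image = img,
    frame_offsets = offs,
    pixel_scale_um = video$pixel_scale_um,
    source_frame_count = n,
    quality_ok = length(warnings) == 0,
    registration_warnings = warnings
  ), class = "nailfold_mosaic")
}
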